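# Relative-pair enumeration and pair contingency tables.

#' Enumerate relative pairs of a given class
#'
#' Derives relative classes purely from parent links and returns the
#' unordered pairs of the requested class.  With `one_per_family` one pair
#' is selected uniformly at random per family (seeded), mirroring designs
#' that keep a single sister pair per family; `exclude_twins` drops
#' full-sibling pairs that share a birth year.
#'
#' @param ped a pedigree table (see [simulate_pedigree()]).
#' @param class relative class label or [relatedness_class()]; `"*_sister"`
#'   labels additionally restrict to female-female pairs.
#' @param sex_filter optional sex (`"F"`/`"M"`) both members must have.
#' @param one_per_family keep at most one (randomly chosen) pair per family.
#' @param exclude_twins drop same-birth-year full-sibling pairs.
#' @param seed integer seed for the per-family selection.
#' @return a `relative_pair_set`: data.frame with columns `fid`, `i`, `j`
#'   and attribute `class`.
#' @export
enumerate_pairs <- function(ped, class, sex_filter = NULL,
                            one_per_family = FALSE, exclude_twins = FALSE,
                            seed = 20191015) {
  cl <- as_relatedness_class(class)
  label0 <- sub("_sister$", "_sibling", cl$label)
  if (grepl("_sister$", cl$label) && is.null(sex_filter)) sex_filter <- "F"
  cp <- classify_pairs(ped)
  cp <- cp[cp$class == label0, , drop = FALSE]
  if (!is.null(sex_filter)) {
    sx <- ped$sex[match(cp$i, ped$iid)]
    sy <- ped$sex[match(cp$j, ped$iid)]
    cp <- cp[sx == sex_filter & sy == sex_filter, , drop = FALSE]
  }
  if (exclude_twins && label0 == "full_sibling") {
    by_i <- ped$birth_year[match(cp$i, ped$iid)]
    by_j <- ped$birth_year[match(cp$j, ped$iid)]
    cp <- cp[by_i != by_j, , drop = FALSE]
  }
  if (one_per_family && nrow(cp)) {
    local_seed_if(seed)
    keep <- unlist(lapply(split(seq_len(nrow(cp)), cp$fid), function(ii)
      if (length(ii) == 1L) ii else sample(ii, 1L)), use.names = FALSE)
    cp <- cp[sort(keep), , drop = FALSE]
  }
  rownames(cp) <- NULL
  out <- cp[, c("fid", "i", "j")]
  attr(out, "class_label") <- cl$label
  class(out) <- c("relative_pair_set", "data.frame")
  out
}

#' Tabulate traits over relative pairs
#'
#' For one trait: counts of pairs with both members affected, both
#' unaffected, and discordant, plus a symmetric 2x2 table (discordant
#' pairs split evenly across the two off-diagonal cells, equivalent to
#' double entry with halved weight).  For two traits: the 16-cell
#' cross-classification of both members' two diagnoses, symmetrized over
#' member order.  Pairs with any missing trait value are dropped and
#' counted.
#'
#' @param pairs a [enumerate_pairs()] result.
#' @param ped the pedigree/phenotype table the pairs refer to.
#' @param traits one or two column names of binary traits in `ped`.
#' @return a `pair_count_table`: for one trait, list with `both_affected`,
#'   `both_unaffected`, `discordant`, `table` (2x2), `n_pairs`,
#'   `n_dropped`; for two traits, list with `cells` (2x2x2x2 array, level
#'   1 = unaffected) and the same bookkeeping.
#' @export
tabulate_pairs <- function(pairs, ped, traits) {
  if (!length(traits) %in% 1:2) stopf("supply one or two trait names")
  miss <- setdiff(traits, names(ped))
  if (length(miss)) stopf("trait(s) not in table: %s",
                          paste(miss, collapse = ", "))
  ii <- match(pairs$i, ped$iid)
  jj <- match(pairs$j, ped$iid)
  V <- lapply(traits, function(tr) cbind(ped[[tr]][ii], ped[[tr]][jj]))
  ok <- Reduce(`&`, lapply(V, function(v) complete.cases(v)))
  n_drop <- sum(!ok)
  V <- lapply(V, function(v) v[ok, , drop = FALSE])
  if (length(traits) == 1L) {
    x <- V[[1]]
    ba <- sum(x[, 1] == 1 & x[, 2] == 1)
    bu <- sum(x[, 1] == 0 & x[, 2] == 0)
    dc <- sum(x[, 1] != x[, 2])
    out <- pair_table_2x2(ba, bu, dc)
    out$n_dropped <- n_drop
    out$trait <- traits
  } else {
    x <- V[[1]]; y <- V[[2]]
    idx <- 1L + x[, 1] + 2L * y[, 1] + 4L * x[, 2] + 8L * y[, 2]
    cells <- array(tabulate(idx, 16L), c(2, 2, 2, 2))
    cells <- symmetrize_cells(cells)
    out <- structure(list(cells = cells, n_pairs = sum(ok),
                          n_dropped = n_drop, traits = traits),
                     class = "pair_count_table")
  }
  attr(out, "class_label") <- attr(pairs, "class_label")
  out
}

# average the two member orderings: cell[x1,y1,x2,y2] <-> cell[x2,y2,x1,y1]
symmetrize_cells <- function(cells) {
  (cells + aperm(cells, c(3, 4, 1, 2))) / 2
}

#' Build a symmetric pair 2x2 table from concordance summaries
#'
#' Published sibling-pair tables often report only the two concordant
#' counts and the total number of discordant pairs; the orientation split
#' of the discordant pairs is not recoverable, so they are divided evenly
#' across the two off-diagonal cells (fractional counts are legitimate
#' weights for the symmetrized multinomial likelihood).
#'
#' @param both_affected,both_unaffected,discordant pair counts (`>= 0`;
#'   fractional allowed).
#' @return a `pair_count_table` (one-trait form).
#' @export
pair_table_2x2 <- function(both_affected, both_unaffected, discordant) {
  if (min(both_affected, both_unaffected, discordant) < 0)
    stopf("counts must be non-negative")
  tab <- matrix(c(both_unaffected, discordant / 2,
                  discordant / 2, both_affected), 2, 2,
                dimnames = list(c("unaff", "aff"), c("unaff", "aff")))
  structure(list(both_affected = both_affected,
                 both_unaffected = both_unaffected,
                 discordant = discordant,
                 table = tab,
                 n_pairs = both_affected + both_unaffected + discordant),
            class = "pair_count_table")
}

#' @export
print.pair_count_table <- function(x, ...) {
  if (!is.null(x$cells)) {
    cat(sprintf("16-cell pair table (%s x %s), %g pairs\n",
                x$traits[1], x$traits[2], x$n_pairs))
  } else {
    cat(sprintf("pair table: %g both affected / %g both unaffected / %g discordant\n",
                x$both_affected, x$both_unaffected, x$discordant))
  }
  invisible(x)
}

#' Prevalence summary stratified by sex and case status
#'
#' Counts and percentages of each trait within strata defined by sex
#' (plus a combined stratum) crossed with a stratifying diagnosis.
#' Percentages are `100 * affected / stratum size`, rounded half-up to one
#' decimal; empty strata yield `NA` with `flagged = TRUE`.
#'
#' @param ped pedigree/phenotype table.
#' @param stratify_by column name of the stratifying binary diagnosis.
#' @param traits trait columns to summarise.
#' @return data.frame with `sex`, stratum level, `n`, `trait`, `count`,
#'   `pct`, `flagged`.
#' @export
prevalence_summary <- function(ped, stratify_by, traits) {
  off <- if (is.null(ped$offspring)) ped else ped[ped$offspring, , drop = FALSE]
  groups <- list(all = rep(TRUE, nrow(off)),
                 F = off$sex == "F",
                 M = off$sex == "M")
  out <- list()
  for (sx in names(groups)) {
    for (lev in c(1L, 0L)) {
      sel <- groups[[sx]] & !is.na(off[[stratify_by]]) &
        off[[stratify_by]] == lev
      n <- sum(sel)
      for (tr in traits) {
        cnt <- sum(off[[tr]][sel] == 1, na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          sex = sx, stratum = lev, n = n, trait = tr, count = cnt,
          pct = if (n > 0) round_half_up(100 * cnt / n, 1) else NA_real_,
          flagged = n == 0, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
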