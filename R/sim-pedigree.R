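# Synthetic pedigree and liability generation.  Families are independent;
# within a family, offspring liabilities are drawn block-wise from the joint
# normal implied by the pairwise relative-class sharing coefficients, which
# matches the pair-based likelihood used downstream.

#' Simulate a multi-family pedigree
#'
#' Generates independent families of configurable structure.  Available
#' structures: `"full"` (two parents, `n_children` full siblings),
#' `"maternal_half"` (one mother, two fathers), `"paternal_half"` (one
#' father, two mothers), `"cousin"` (a grandparental couple, two parent
#' full-siblings each with a spouse and `n_children` children, yielding
#' first-cousin pairs across the two nuclear units) and `"twin"` (a full
#' sibship sharing one birth year).  The four analysis relative classes are
#' recoverable from the emitted parent links alone.
#'
#' @param n_families number of families (>= 1).
#' @param pattern either a named probability vector over the structure
#'   types above, or a shortcut string: `"two_full_sisters"`,
#'   `"maternal_half_sisters"`, `"twin_pairs"`, `"mixed"`.
#' @param n_children children per nuclear family unit.
#' @param sexes `"random"` (Bernoulli 1/2) or `"female"`.
#' @param birth_range inclusive birth-year range for the offspring
#'   generation.
#' @param seed integer seed; every stochastic operation in the package
#'   takes one explicitly.
#' @return a `data.frame` (class `pedigree_table`) with columns `iid`,
#'   `fid`, `mid`, `pid`, `sex` (`"F"`/`"M"`), `birth_year` and
#'   `offspring` (`TRUE` for the analysis generation).
#' @examples
#' ped <- simulate_pedigree(3, pattern = "two_full_sisters", seed = 1)
#' @export
simulate_pedigree <- function(n_families,
                              pattern = "mixed",
                              n_children = 2,
                              sexes = c("random", "female"),
                              birth_range = c(1970, 2005),
                              seed = 20191015) {
  if (!is_count(n_families)) stopf("n_families must be a positive integer")
  sexes <- match.arg(sexes)
  known_types <- c("full", "maternal_half", "paternal_half", "cousin",
                   "twin")
  if (is.character(pattern) && length(pattern) == 1L &&
      pattern %in% known_types) {
    pattern <- setNames(1, pattern)
  } else if (is.character(pattern) && length(pattern) == 1L) {
    pattern <- switch(pattern,
      two_full_sisters      = { sexes <- "female"; c(full = 1) },
      maternal_half_sisters = { sexes <- "female"; c(maternal_half = 1) },
      twin_pairs            = c(twin = 1),
      mixed = c(full = .45, maternal_half = .2, paternal_half = .15,
                cousin = .2),
      stopf("unknown pattern shortcut '%s'", pattern))
  }
  if (is.null(names(pattern)) || !all(names(pattern) %in% known_types))
    stopf("pattern must be named with structure types: %s",
          paste(known_types, collapse = ", "))
  pattern <- pattern / sum(pattern)
  local_seed_if(seed)

  struct <- sample(names(pattern), n_families, replace = TRUE, prob = pattern)
  fid_all <- sprintf("F%06d", seq_len(n_families))
  yrs <- seq.int(birth_range[1], birth_range[2])
  draw_sex <- function(k) {
    if (sexes == "female") rep("F", k) else sample(c("F", "M"), k, TRUE)
  }
  # n x k matrix of birth years, distinct within a row where possible
  draw_year_mat <- function(n, k) {
    Y <- matrix(sample(yrs, n * k, TRUE), n, k)
    if (k > 1L && length(yrs) >= k) {
      for (it in 1:20) {
        dup <- which(apply(Y, 1, anyDuplicated) > 0)
        if (!length(dup)) break
        Y[dup, ] <- matrix(sample(yrs, length(dup) * k, TRUE),
                           length(dup), k)
      }
    }
    Y
  }
  blocks <- list()
  add <- function(fid, tag, mid, pid, sex, by, off, ord) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      iid = paste0(fid, "_", tag), fid = fid,
      mid = mid, pid = pid, sex = sex, birth_year = by,
      offspring = off, ord = ord, stringsAsFactors = FALSE)
  }
  for (st in unique(struct)) {
    fid <- fid_all[struct == st]
    n <- length(fid)
    py <- birth_range[1] - sample(20:35, n, TRUE)
    if (st %in% c("full", "twin")) {
      add(fid, "m", NA, NA, "F", py, FALSE, 1L)
      add(fid, "p", NA, NA, "M", py, FALSE, 2L)
      Y <- if (st == "twin")
        matrix(sample(yrs, n, TRUE), n, n_children)
      else draw_year_mat(n, n_children)
      for (j in seq_len(n_children))
        add(fid, paste0("c", j), paste0(fid, "_m"), paste0(fid, "_p"),
            draw_sex(n), Y[, j], TRUE, 2L + j)
    } else if (st %in% c("maternal_half", "paternal_half")) {
      k1 <- max(ceiling(n_children / 2), 1L)
      k2 <- max(n_children - k1, 1L)
      kids <- k1 + k2
      Y <- draw_year_mat(n, kids)
      if (st == "maternal_half") {
        add(fid, "m", NA, NA, "F", py, FALSE, 1L)
        add(fid, "p1", NA, NA, "M", py, FALSE, 2L)
        add(fid, "p2", NA, NA, "M", py, FALSE, 3L)
        for (j in seq_len(kids))
          add(fid, paste0("c", j), paste0(fid, "_m"),
              paste0(fid, "_", if (j <= k1) "p1" else "p2"),
              draw_sex(n), Y[, j], TRUE, 3L + j)
      } else {
        add(fid, "p", NA, NA, "M", py, FALSE, 1L)
        add(fid, "m1", NA, NA, "F", py, FALSE, 2L)
        add(fid, "m2", NA, NA, "F", py, FALSE, 3L)
        for (j in seq_len(kids))
          add(fid, paste0("c", j),
              paste0(fid, "_", if (j <= k1) "m1" else "m2"),
              paste0(fid, "_p"), draw_sex(n), Y[, j], TRUE, 3L + j)
      }
    } else {                                     # cousin: three generations
      k <- n_children
      gy <- py - 28
      psx1 <- draw_sex(n); psx2 <- draw_sex(n)
      add(fid, "gm", NA, NA, "F", gy, FALSE, 1L)
      add(fid, "gp", NA, NA, "M", gy, FALSE, 2L)
      add(fid, "a1", paste0(fid, "_gm"), paste0(fid, "_gp"), psx1, py,
          FALSE, 3L)
      add(fid, "a2", paste0(fid, "_gm"), paste0(fid, "_gp"), psx2, py,
          FALSE, 4L)
      add(fid, "s1", NA, NA, ifelse(psx1 == "F", "M", "F"), py, FALSE, 5L)
      add(fid, "s2", NA, NA, ifelse(psx2 == "F", "M", "F"), py, FALSE, 6L)
      # unit u: mother is whichever of (au, su) is female
      u1m <- paste0(fid, "_", ifelse(psx1 == "F", "a1", "s1"))
      u1p <- paste0(fid, "_", ifelse(psx1 == "F", "s1", "a1"))
      u2m <- paste0(fid, "_", ifelse(psx2 == "F", "a2", "s2"))
      u2p <- paste0(fid, "_", ifelse(psx2 == "F", "s2", "a2"))
      Y <- draw_year_mat(n, 2L * k)
      for (j in seq_len(k))
        add(fid, paste0("c", j), u1m, u1p, draw_sex(n), Y[, j], TRUE, 6L + j)
      for (j in seq_len(k))
        add(fid, paste0("c", k + j), u2m, u2p, draw_sex(n), Y[, k + j],
            TRUE, 6L + k + j)
    }
  }
  ped <- do.call(rbind, blocks)
  ped <- ped[order(ped$fid, ped$ord), , drop = FALSE]
  ped$ord <- NULL
  rownames(ped) <- NULL
  if (anyDuplicated(ped$iid)) stopf("internal error: duplicate ids")
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# pairwise relative classes among offspring, derived from parent links only.
# Returns data.frame(fid, i, j, class); vectorized over all families by
# grouping them by sibship size (the per-pair logic is pure vector ops).
classify_pairs <- function(ped) {
  off <- if (is.null(ped$offspring)) ped
         else ped[ped$offspring, , drop = FALSE]
  empty <- data.frame(fid = character(), i = character(), j = character(),
                      class = character(), stringsAsFactors = FALSE)
  if (nrow(off) < 2L) return(empty)
  fid_f <- factor(off$fid, levels = unique(off$fid))
  o <- order(as.integer(fid_f))
  off <- off[o, , drop = FALSE]
  sizes <- tabulate(fid_f)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  a <- integer(0); b <- integer(0)
  for (m in unique(sizes[sizes >= 2L])) {
    fams <- which(sizes == m)
    cmb <- utils::combn(m, 2L)
    base <- rep(starts[fams], each = ncol(cmb))
    a <- c(a, base + rep(cmb[1, ], length(fams)))
    b <- c(b, base + rep(cmb[2, ], length(fams)))
  }
  if (!length(a)) return(empty)
  mid <- off$mid; pid <- off$pid
  same_m <- !is.na(mid[a]) & !is.na(mid[b]) & mid[a] == mid[b]
  same_p <- !is.na(pid[a]) & !is.na(pid[b]) & pid[a] == pid[b]
  cls <- rep(NA_character_, length(a))
  cls[same_m & same_p] <- "full_sibling"
  cls[same_m & !same_p] <- "maternal_half_sibling"
  cls[!same_m & same_p] <- "paternal_half_sibling"
  rest <- which(is.na(cls))
  if (length(rest)) {
    # cousins: a parent of one is a full sibling of a parent of the other
    par_mid <- function(q) ped$mid[match(q, ped$iid)]
    par_pid <- function(q) ped$pid[match(q, ped$iid)]
    full_sibs <- function(q1, q2) {
      m1 <- par_mid(q1); p1 <- par_pid(q1)
      m2 <- par_mid(q2); p2 <- par_pid(q2)
      !is.na(q1) & !is.na(q2) & q1 != q2 &
        !is.na(m1) & !is.na(m2) & m1 == m2 &
        !is.na(p1) & !is.na(p2) & p1 == p2
    }
    ra <- a[rest]; rb <- b[rest]
    isc <- full_sibs(mid[ra], mid[rb]) | full_sibs(mid[ra], pid[rb]) |
      full_sibs(pid[ra], mid[rb]) | full_sibs(pid[ra], pid[rb])
    cls[rest[isc]] <- "cousin"
  }
  keep <- !is.na(cls)
  if (!any(keep)) return(empty)
  res <- data.frame(fid = off$fid[a[keep]], i = off$iid[a[keep]],
                    j = off$iid[b[keep]], class = cls[keep],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Simulate liabilities for a pedigree under a bivariate architecture
#'
#' Draws per-individual latent liabilities for the two traits of an
#' [architecture_spec()] from the family-block multivariate normal implied
#' by the pairwise relative-class coefficients: the expected cross-relative
#' same-trait covariance of e.g. a full-sister pair is
#' `.5*a2 + .25*d2 + c2`.  Only the offspring generation receives
#' liabilities (founder/parent rows are `NA`); families are independent.
#'
#' @param ped a [simulate_pedigree()] table.
#' @param spec an [architecture_spec()].
#' @param seed integer seed.
#' @param c_cousin,c_paternal_half shared-environment coefficients for
#'   cousins and paternal half-siblings (not identified by the sister
#'   design; defaults 0).
#' @return numeric matrix `nrow(ped)` x 2 with the trait names of `spec`.
#' @export
simulate_liabilities <- function(ped, spec, seed = 20191015,
                                 c_cousin = 0, c_paternal_half = 0) {
  stopifnot(inherits(spec, "architecture_spec"))
  local_seed_if(seed)
  cp <- classify_pairs(ped)
  off_rows <- if (is.null(ped$offspring)) seq_len(nrow(ped))
              else which(ped$offspring)
  off_ids <- ped$iid[off_rows]
  fam <- split(seq_along(off_ids), ped$fid[off_rows])
  classes <- list(
    full_sibling = relatedness_class("full_sibling"),
    maternal_half_sibling = relatedness_class("maternal_half_sibling"),
    paternal_half_sibling = relatedness_class("paternal_half_sibling",
                                              c_paternal_half),
    cousin = relatedness_class("cousin", c_cousin))
  SA <- matrix(c(spec$a2[1], spec$covA, spec$covA, spec$a2[2]), 2)
  SD <- matrix(c(spec$d2[1], spec$covD, spec$covD, spec$d2[2]), 2)
  SC <- matrix(c(spec$c2[1], spec$covC, spec$covC, spec$c2[2]), 2)
  SE <- matrix(c(spec$e2[1], spec$covE, spec$covE, spec$e2[2]), 2)

  # group families by their relationship-structure signature so the Cholesky
  # factor is computed once per structure and sampling is one matrix product
  fid_off <- ped$fid[off_rows]
  fam_len <- lengths(fam)
  pos_in_fam <- integer(length(off_ids))
  pos_in_fam[unlist(fam, use.names = FALSE)] <-
    sequence(fam_len)
  names(pos_in_fam) <- off_ids

  # per-family structure signature, built by grouped string aggregation
  if (nrow(cp)) {
    pdt <- data.table::data.table(
      fid = cp$fid, pi_ = pos_in_fam[cp$i], pj = pos_in_fam[cp$j],
      cli = match(cp$class, names(classes)))
    data.table::setorder(pdt, fid, pi_, pj)
    sig_dt <- pdt[, list(sig = paste(pi_, pj, cli, collapse = ";")),
                  by = "fid"]
    sig_map <- setNames(sig_dt$sig, sig_dt$fid)
  } else sig_map <- character(0)
  sig <- paste0("m", fam_len)
  hit <- names(fam) %in% names(sig_map)
  sig[hit] <- paste0(sig[hit], "|", sig_map[names(fam)[hit]])
  pdt_first <- if (nrow(cp)) split(seq_len(nrow(pdt)), pdt$fid) else list()

  liab <- matrix(NA_real_, nrow(ped), 2,
                 dimnames = list(NULL, spec$traits))
  for (s in unique(sig)) {
    gset <- which(sig == s)
    m <- fam_len[gset[1]]
    KA <- KD <- KC <- diag(m)
    rows1 <- pdt_first[[names(fam)[gset[1]]]]
    if (!is.null(rows1)) {
      for (r in rows1) {
        cl <- classes[[pdt$cli[r]]]
        a <- pdt$pi_[r]; b <- pdt$pj[r]
        KA[a, b] <- KA[b, a] <- cl$kA
        KD[a, b] <- KD[b, a] <- cl$kD
        KC[a, b] <- KC[b, a] <- cl$kC
      }
    }
    Sig <- kronecker(KA, SA) + kronecker(KD, SD) + kronecker(KC, SC) +
      kronecker(diag(m), SE)
    L <- tryCatch(chol(Sig), error = function(e)
      stopf("implied family covariance is not positive definite (structure %s)", s))
    Z <- matrix(rnorm(2 * m * length(gset)), nrow = 2 * m)
    X <- crossprod(L, Z)                    # (2m) x n_fam draws
    rows_vec <- off_rows[unlist(fam[gset], use.names = FALSE)]
    liab[rows_vec, 1] <- as.vector(X[seq(1, 2 * m, by = 2), , drop = FALSE])
    liab[rows_vec, 2] <- as.vector(X[seq(2, 2 * m, by = 2), , drop = FALSE])
  }
  liab
}

#' Threshold liabilities into binary diagnoses
#'
#' An individual is diagnosed iff their liability exceeds the standard
#' normal quantile at `1 - prevalence`.
#'
#' @param liabilities numeric vector or matrix of liabilities.
#' @param prevalence target population prevalence(s) in (0, 1); recycled
#'   across matrix columns.
#' @return integer vector/matrix of 0/1 diagnoses (`NA` preserved).
#' @export
threshold_diagnose <- function(liabilities, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stopf("prevalence must lie strictly in (0, 1)")
  thr <- qnorm(1 - prevalence)
  if (is.matrix(liabilities)) {
    thr <- rep_len(thr, ncol(liabilities))
    out <- liabilities > rep(thr, each = nrow(liabilities))
  } else {
    out <- liabilities > thr
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a diagnosed cohort in one call
#'
#' Convenience wrapper: pedigree + liabilities + thresholded diagnoses for
#' the two traits of `spec`, returned as a phenotype table ready for pair
#' enumeration and regression.
#'
#' @inheritParams simulate_liabilities
#' @inheritParams simulate_pedigree
#' @param ... passed to [simulate_pedigree()].
#' @return a `pedigree_table` with added `dx_<trait>` columns.
#' @export
simulate_cohort <- function(n_families, spec, seed = 20191015, ...) {
  ped <- simulate_pedigree(n_families, seed = seed, ...)
  liab <- simulate_liabilities(ped, spec, seed = derive_seed(seed, 1))
  dx <- threshold_diagnose(liab, spec$prevalence)
  for (k in 1:2) ped[[paste0("dx_", spec$traits[k])]] <- dx[, k]
  ped
}

#' Simulate 16-cell sister-pair tables directly
#'
#' Fast path for parameter-recovery studies: draws `n_pairs` independent
#' pairs of the given relative class from the 4-dimensional liability
#' normal implied by `spec`, thresholds them, and cross-tabulates the
#' (trait X, trait Y) diagnoses of both pair members.
#'
#' @param n_pairs named integer vector, e.g.
#'   `c(full_sister = 1e5, maternal_half_sister = 2e4)`.
#' @param spec an [architecture_spec()].
#' @param seed integer seed.
#' @return named list of 2x2x2x2 count arrays (dims: member-1 trait X,
#'   member-1 trait Y, member-2 trait X, member-2 trait Y; level 1 =
#'   unaffected, level 2 = affected).
#' @export
simulate_pair_tables <- function(n_pairs, spec, seed = 20191015) {
  stopifnot(inherits(spec, "architecture_spec"))
  local_seed_if(seed)
  tx <- qnorm(1 - spec$prevalence[1])
  ty <- qnorm(1 - spec$prevalence[2])
  out <- vector("list", length(n_pairs))
  names(out) <- names(n_pairs)
  for (cl in names(n_pairs)) {
    R <- pair_model_matrix(spec, relatedness_class(cl))
    L <- chol(R)
    n <- n_pairs[[cl]]
    X <- crossprod(L, matrix(rnorm(4 * n), 4))
    aff <- cbind(X[1, ] > tx, X[2, ] > ty, X[3, ] > tx, X[4, ] > ty)
    idx <- 1L + aff %*% c(1L, 2L, 4L, 8L)
    cnt <- tabulate(idx, nbins = 16L)
    out[[cl]] <- array(cnt, c(2, 2, 2, 2))
  }
  out
}
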