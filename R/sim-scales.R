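# Item-level symptom-scale simulation.  Items load on one latent symptom
# factor that correlates with the supplied genetic value; continuous item
# scores are cut into the instrument's legal response categories.  Because
# categorization attenuates inter-item Pearson correlations, the generator
# de-attenuates the latent correlation by the closed-form categorization
# factor so the emitted items hit the requested Cronbach alpha.

scale_def <- function(scale = c("atac", "edi")) {
  scale <- match.arg(scale)
  if (scale == "atac") {
    list(name = "atac",
         items = c(paste0("inatt", 1:9), paste0("hyp", 1:10)),
         values = c(0, 0.5, 1),
         # parent-report response mix: mostly "no"
         probs = c(0.85, 0.11, 0.04))
  } else {
    list(name = "edi",
         items = c(paste0("dt", 1:7), paste0("bul", 1:7), paste0("bd", 1:8)),
         values = 1:6,
         probs = c(0.45, 0.25, 0.12, 0.09, 0.05, 0.04))
  }
}

# Pearson correlation between two items after both are categorized at
# thresholds tau, as a function of their latent bivariate-normal
# correlation r.  Exact: cell probabilities by inclusion-exclusion of the
# bivariate CDF over the category grid.
categorized_corr <- function(r, values, probs) {
  K <- length(values)
  tau <- c(-Inf, qnorm(cumsum(probs))[-K], Inf)
  Fm <- outer(tau, tau, function(a, b) pbvn(a, b, r))
  P <- Fm[-1, -1] - Fm[-(K + 1), -1] - Fm[-1, -(K + 1)] + Fm[-(K + 1), -(K + 1)]
  mu <- sum(values * probs)
  v <- sum(values^2 * probs) - mu^2
  (as.numeric(t(values) %*% P %*% values) - mu^2) / v
}

# latent correlation needed so the categorized items correlate at r_target
latent_corr_for <- function(r_target, values, probs) {
  if (r_target <= 0) return(0)
  hi <- categorized_corr(0.995, values, probs)
  if (r_target >= hi) return(NA_real_)
  stats::uniroot(function(r) categorized_corr(r, values, probs) - r_target,
                 c(0, 0.995), tol = 1e-9)$root
}

#' Simulate item-level symptom-scale responses
#'
#' Generates discrete item responses for a parent-report ADHD inventory
#' (19 items on 0 / 0.5 / 1: 9 inattention + 10 hyperactivity) or a
#' self-report eating-disorder inventory (22 items on 1..6: 7 drive for
#' thinness + 7 bulimia + 8 body dissatisfaction).  Items are parallel
#' measures of a single latent symptom factor `T = effect * g +
#' sqrt(1-effect^2) * u`; the latent inter-item correlation is chosen so
#' the standardized Cronbach alpha of the *emitted, categorized* items
#' matches `target_alpha`.
#'
#' @param g numeric vector of (standardized) genetic values.
#' @param scale `"atac"` or `"edi"`.
#' @param effect correlation between the latent symptom factor and `g`.
#' @param target_alpha desired standardized Cronbach alpha of the emitted
#'   items.
#' @param category_probs optional response-category probabilities
#'   overriding the instrument defaults.
#' @param seed integer seed.
#' @return numeric matrix `length(g)` x n-items with legal response values;
#'   attributes `scale` and `latent_r` (the de-attenuated latent
#'   correlation used).
#' @export
simulate_symptom_scales <- function(g, scale = c("atac", "edi"),
                                    effect = 0.1, target_alpha = 0.9,
                                    category_probs = NULL,
                                    seed = 20191015) {
  def <- scale_def(match.arg(scale))
  if (!is.null(category_probs)) {
    if (length(category_probs) != length(def$values) ||
        any(category_probs <= 0) || abs(sum(category_probs) - 1) > 1e-8)
      stopf("category_probs must be %d positive values summing to 1",
            length(def$values))
    def$probs <- category_probs
  }
  if (abs(effect) > 1) stopf("effect must lie in [-1, 1]")
  if (target_alpha <= 0 || target_alpha >= 1)
    stopf("target_alpha must lie in (0, 1)")
  k <- length(def$items)
  # invert alpha = k r / (1 + (k-1) r), then undo the categorization
  # attenuation by inverting the exact categorized-correlation curve
  rbar <- target_alpha / (k - (k - 1) * target_alpha)
  r_lat <- latent_corr_for(rbar, def$values, def$probs)
  if (is.na(r_lat)) {
    warning("target alpha unattainable after categorization; clamping")
    r_lat <- 0.995
  }
  local_seed_if(seed)
  n <- length(g)
  gs <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, n)
  Tn <- effect * gs + sqrt(max(1 - effect^2, 0)) * rnorm(n)
  lat <- sqrt(r_lat) * Tn +
    sqrt(1 - r_lat) * matrix(rnorm(n * k), n, k)
  tau <- qnorm(cumsum(def$probs))[-length(def$probs)]
  resp <- matrix(def$values[findInterval(as.vector(lat), tau) + 1L], n, k)
  colnames(resp) <- def$items
  attr(resp, "scale") <- def$name
  attr(resp, "latent_r") <- r_lat
  resp
}
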