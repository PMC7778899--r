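# Gaussian-model driverness score: the cumulative normal probability of an
# entity's -log2(FDR) after Z-transformation within its entity class.

#' Gaussian-model driverness scores from FDRs
#'
#' For a set of entities of one class (all tested mutations, all tested
#' genes, or all tested pathways of one cohort), each entity's FDR is
#' transformed to `x = -log2(FDR)`; the class mean `mu` and standard
#' deviation `sigma` of `x` are computed over the input population; and
#' the score is the standard normal cumulative probability
#' `Phi((x - mu) / sigma)`. Scores lie in (0, 1), increase strictly with
#' `x` (so their ranking equals the ranking by decreasing significance),
#' and a score of 0.5 marks an entity at the class mean. Higher scores
#' indicate greater driver potential relative to the class.
#'
#' @param fdrs Named numeric vector (entity -> FDR in `(0, 1]`; FDR = 1
#'   gives x = 0, a valid minimum) of length >= 2. FDRs of 0 are floored
#'   to `fdr_floor` with a warning.
#' @param sd_type `"population"` (divide by n, default — deterministic on
#'   tiny sets) or `"sample"` (n - 1).
#' @param fdr_floor Floor applied to zero/underflowed FDRs, default 1e-300.
#' @return Data frame: `entity`, `fdr`, `x`, `mu`, `sigma`, `score`.
#' @export
driverness_score <- function(fdrs, sd_type = c("population", "sample"),
                             fdr_floor = 1e-300) {
  sd_type <- match.arg(sd_type)
  if (length(fdrs) < 2) {
    stop("driverness_score needs at least two entities (the class defines",
         " the Gaussian)")
  }
  entity <- names(fdrs)
  if (is.null(entity)) entity <- as.character(seq_along(fdrs))
  fdrs <- as.numeric(fdrs)
  if (any(fdrs < 0 | fdrs > 1, na.rm = TRUE)) {
    stop("FDRs must lie in [0, 1]")
  }
  if (any(fdrs == 0, na.rm = TRUE)) {
    warning("FDR of 0 floored to ", fdr_floor)
    fdrs[fdrs == 0] <- fdr_floor
  }
  x <- -log2(fdrs)
  mu <- mean(x)
  n <- length(x)
  sigma <- if (sd_type == "population") {
    sqrt(sum((x - mu)^2) / n)
  } else {
    stats::sd(x)
  }
  if (sigma == 0) {
    warning("all FDRs identical (sigma = 0); every score set to 0.5")
    score <- rep(0.5, n)
  } else {
    score <- stats::pnorm((x - mu) / sigma)
  }
  data.frame(entity = entity, fdr = fdrs, x = x, mu = mu, sigma = sigma,
             score = score, stringsAsFactors = FALSE)
}
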