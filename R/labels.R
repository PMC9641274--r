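#' Histological label scheme
#'
#' Thresholds translating the histology percentages into classes: burns with
#' dermal burn depth below `spt_upper` percent are superficial
#' partial-thickness (SPT), between `spt_upper` and `dpt_upper` (inclusive)
#' deep partial-thickness (DPT), above `dpt_upper` full-thickness (FT);
#' healthy sites are H.  Sites at `fr_threshold` percent day-28
#' re-epithelialization are fully re-epithelialized (FR), all others
#' none-or-partially re-epithelialized (NPR).
#'
#' @param spt_upper SPT/DPT boundary (% dermal burn, default 60).
#' @param dpt_upper DPT/FT boundary (% dermal burn, default 90).
#' @param fr_threshold re-epithelialization percentage defining FR
#'   (default 100).
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(spt_upper = 60, dpt_upper = 90, fr_threshold = 100) {
  if (!(spt_upper > 0 && spt_upper < dpt_upper && dpt_upper < 100))
    config_error("need 0 < spt_upper < dpt_upper < 100")
  structure(list(spt_upper = spt_upper, dpt_upper = dpt_upper,
                 fr_threshold = fr_threshold),
            class = "label_scheme")
}

#' Assign severity and healing classes to a site
#'
#' Boundary convention: the DPT interval is closed (`60 <= dermal <= 90` with
#' the default scheme), matching the strict `< 60` SPT and `> 90` FT rules.
#'
#' @param label a [site_label()].
#' @param scheme a [label_scheme()].
#' @return A list with `severity` (factor level `"H"`, `"SPT"`, `"DPT"`,
#'   `"FT"`) and `healing` (`"FR"` or `"NPR"`).
#' @export
assign_labels <- function(label, scheme = label_scheme()) {
  stopifnot(inherits(label, "site_label"), inherits(scheme, "label_scheme"))
  d <- label$dermal_burn_pct; r <- label$reepi_pct_day28
  if (!is.finite(d) || d < 0 || d > 100 || !is.finite(r) || r < 0 || r > 100)
    label_error("percentages must lie in [0, 100]")
  severity <- if (label$etiology == "healthy") "H"
  else if (d < scheme$spt_upper) "SPT"
  else if (d <= scheme$dpt_upper) "DPT"
  else "FT"
  healing <- if (r >= scheme$fr_threshold) "FR" else "NPR"
  list(severity = severity, healing = healing)
}

#' Stratified train/test split at the observation level
#'
#' Random split at region-of-interest granularity, stratified by class so
#' the unbalanced smaller classes survive the 20% draw.
#'
#' @param y factor (or vector) of class labels, one per observation.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed; the split is reproducible given the seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_observations <- function(y, train_fraction = 0.8, seed = NULL) {
  y <- as.factor(y)
  if (any(table(y) < 2))
    partition_error("every class needs at least 2 observations to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    config_error("'train_fraction' must be in (0, 1)")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}
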