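#' Growth-normalized metabolite exchange rate
#'
#' Estimates the consumption or excretion rate alpha of a metabolite from a
#' spent-media time course, normalised per 10^6 cells per hour:
#'
#'   alpha = 10^6 * dM / integral_0^t X(tau) dtau
#'
#' where dM is the change in metabolite amount in the well (nmol) and X(tau)
#' is the cell number, modeled as exponential growth between consecutive
#' observed counts (k = ln(X2/X1) / dt on each interval, so the integral is
#' X1 * (exp(k dt) - 1) / k, with the continuous limit X1 * dt as k -> 0).
#' Positive alpha means net excretion (the amount in the medium increases),
#' negative means consumption.
#'
#' @param course tibble with columns `t_hours` (strictly increasing, first
#'   value 0), `cell_count` (> 0), `metabolite_nmol`, and optionally
#'   `blank_nmol` (amounts in a cell-free well)
#' @param blank_correct subtract the cell-free well's change in amount
#'   first, removing spontaneous degradation/evaporation (off by default)
#' @return alpha in nmol per 10^6 cells per hour (length-1 numeric)
#' @examples
#' # constant 1e6 cells, +10 nmol over 10 h -> alpha = +1
#' exchange_rate(tibble::tibble(
#'   t_hours = c(0, 10), cell_count = 1e6, metabolite_nmol = c(100, 110)))
#' @export
exchange_rate <- function(course, blank_correct = FALSE) {
  course <- as_tibble(course)
  need <- c("t_hours", "cell_count", "metabolite_nmol")
  missing <- setdiff(need, names(course))
  if (length(missing)) {
    abort(sprintf("`course` lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(course) < 2) abort("`course` needs at least two timepoints.")
  t <- course$t_hours
  X <- course$cell_count
  if (t[[1]] != 0) abort("the first timepoint must be t = 0.")
  if (any(diff(t) <= 0)) abort("`t_hours` must be strictly increasing.")
  if (any(!is.finite(X)) || any(X <= 0)) abort("cell counts must be > 0.")

  dM <- course$metabolite_nmol[[nrow(course)]] - course$metabolite_nmol[[1]]
  if (blank_correct) {
    if (!"blank_nmol" %in% names(course)) {
      abort("`blank_correct = TRUE` requires a `blank_nmol` column.")
    }
    dM <- dM - (course$blank_nmol[[nrow(course)]] - course$blank_nmol[[1]])
  }

  # cell-hours: piecewise-exponential integral of X over the course
  cell_hours <- 0
  for (i in seq_len(nrow(course) - 1)) {
    dt <- t[[i + 1]] - t[[i]]
    k <- log(X[[i + 1]] / X[[i]]) / dt
    cell_hours <- cell_hours +
      if (abs(k * dt) < 1e-9) X[[i]] * dt else X[[i]] * (exp(k * dt) - 1) / k
  }
  1e6 * dM / cell_hours
}

#' Succinate dehydrogenase activity from a colorimetric assay reading
#'
#' Activity is `B / (dT * V) * D`, in nmol DCIP reduced per minute per
#' microliter of sample: `B` is the amount of reduced DCIP read off the
#' standard curve (nmol), `dT` the reaction time (min), `V` the sample
#' volume added to the reaction well (ul) and `D` the dilution factor.
#' Vectorised over readings.
#'
#' @param B reduced DCIP from the standard curve (nmol, >= 0)
#' @param delta_t_min reaction time (min, > 0)
#' @param volume_ul sample volume (ul, > 0)
#' @param dilution dilution factor (>= 1, default 1)
#' @return activity in nmol / min / ul
#' @export
sdh_activity <- function(B, delta_t_min, volume_ul, dilution = 1) {
  if (any(!is.finite(B)) || any(B < 0)) abort("`B` must be >= 0.")
  if (any(!is.finite(delta_t_min)) || any(delta_t_min <= 0)) {
    abort("`delta_t_min` must be > 0.")
  }
  if (any(!is.finite(volume_ul)) || any(volume_ul <= 0)) {
    abort("`volume_ul` must be > 0.")
  }
  if (any(!is.finite(dilution)) || any(dilution < 1)) {
    abort("`dilution` must be >= 1.")
  }
  B / (delta_t_min * volume_ul) * dilution
}

# canonical phase labels and the synonyms accepted in input tables
.ocr_phases <- list(
  basal = c("basal"),
  oligomycin = c("oligomycin", "post-oligomycin", "oligo"),
  fccp = c("fccp", "post-fccp"),
  rotenone = c("rotenone", "post-rotenone", "rotenone-myxothiazol",
               "post-rotenone-myxothiazol", "rot/myx", "antimycin"))

normalize_phase <- function(phase) {
  p <- tolower(trimws(phase))
  out <- rep(NA_character_, length(p))
  for (canon in names(.ocr_phases)) {
    out[p %in% .ocr_phases[[canon]]] <- canon
  }
  out
}

#' Respiratory parameters from an oxygen-consumption trace
#'
#' Summarises a mitochondrial stress test: OCR measured at baseline, then
#' after sequential injection of oligomycin (ATP-synthase inhibitor), FCCP
#' (uncoupler driving maximal respiration) and rotenone/myxothiazol
#' (complex I/III inhibitors abolishing mitochondrial respiration).
#' Measurements are averaged within each phase, then:
#'
#' * `non_mitochondrial` = mean(rotenone phase)
#' * `basal` = mean(basal) - non_mitochondrial
#' * `maximal` = mean(FCCP) - non_mitochondrial
#' * `atp_linked` = mean(basal) - mean(oligomycin)
#' * `reserve_capacity_abs` = maximal - basal (the spare respiratory
#'   capacity); `reserve_capacity_pct` = 100 * (maximal - basal) / basal
#'
#' When FCCP fails to raise OCR above basal the spare capacity is
#' nonexistent: the reserve is reported as 0 with `reserve_nonexistent =
#' TRUE`.
#'
#' @param trace tibble with columns `phase` (basal / oligomycin / fccp /
#'   rotenone, common synonyms accepted) and `ocr` (non-negative,
#'   pre-normalised e.g. per protein)
#' @return one-row tibble of the parameters above
#' @export
respiratory_params <- function(trace) {
  trace <- as_tibble(trace)
  if (!all(c("phase", "ocr") %in% names(trace))) {
    abort("`trace` must have columns `phase` and `ocr`.")
  }
  if (any(!is.finite(trace$ocr)) || any(trace$ocr < 0)) {
    abort("OCR values must be finite and >= 0.")
  }
  canon <- normalize_phase(trace$phase)
  if (anyNA(canon)) {
    abort(sprintf("unrecognised phase label(s): %s",
                  paste(unique(trace$phase[is.na(canon)]), collapse = ", ")))
  }
  means <- tapply(trace$ocr, factor(canon, levels = names(.ocr_phases)),
                  mean)
  absent <- names(means)[is.na(means)]
  if (length(absent)) {
    abort(sprintf("trace is missing required phase(s): %s",
                  paste(absent, collapse = ", ")))
  }
  non_mito <- unname(means[["rotenone"]])
  basal <- unname(means[["basal"]]) - non_mito
  maximal <- unname(means[["fccp"]]) - non_mito
  atp_linked <- unname(means[["basal"]]) - unname(means[["oligomycin"]])
  reserve_abs <- maximal - basal
  nonexistent <- reserve_abs <= 0
  if (nonexistent) reserve_abs <- 0
  reserve_pct <- if (reserve_abs == 0) 0 else 100 * reserve_abs / basal
  tibble(
    basal = basal, atp_linked = atp_linked, maximal = maximal,
    reserve_capacity_abs = reserve_abs, reserve_capacity_pct = reserve_pct,
    non_mitochondrial = non_mito, reserve_nonexistent = nonexistent)
}
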