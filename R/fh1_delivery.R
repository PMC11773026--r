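#' Normalized fluorescence of a formin-assembled filament segment
#'
#' The intensity of a formin-assembled (dim) segment divided by the
#' intensity of a control segment of the same filament grown after the
#' formin dissociated. Both intensities are background-subtracted arbitrary
#' units; values above 1 can occur through measurement noise and are
#' returned as-is (clamping happens in the fraction calculations).
#'
#' @param formin_intensity Intensity of the formin-assembled segment (> 0).
#' @param control_intensity Intensity of the control segment (> 0).
#' @return Dimensionless intensity ratio. Vectorized.
#' @export
normalized_fluorescence <- function(formin_intensity, control_intensity) {
  stopifnot(is.numeric(formin_intensity), is.numeric(control_intensity))
  if (any(control_intensity <= 0))
    stop("control_intensity must be > 0")
  if (any(formin_intensity < 0))
    stop("formin_intensity must be >= 0")
  formin_intensity / control_intensity
}

clamp01 <- function(x, what) {
  out <- pmin(pmax(x, 0), 1)
  n_clamped <- sum(out != x)
  if (n_clamped > 0)
    warning(sprintf("%d %s value(s) outside [0, 1] clamped", n_clamped, what),
            call. = FALSE)
  out
}

#' Fraction of unlabeled subunits delivered by the FH1 domain
#'
#' FH1-delivered subunits come from profilin-actin, whose profilin occludes
#' incorporation of labeled monomers less efficiently than unlabeled ones in
#' proportion to their binding. Dimming of the formin-assembled segment
#' relative to the control segment measures the unlabeled ("black")
#' FH1-delivered fraction directly: `fh1_black = 1 - normalized`.
#' Noise-driven values outside `[0, 1]` are clamped with a warning.
#'
#' @param normalized Normalized fluorescence ratio (>= 0). Vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
fh1_fraction_black <- function(normalized) {
  stopifnot(is.numeric(normalized))
  if (any(normalized < 0)) stop("normalized fluorescence must be >= 0")
  clamp01(1 - normalized, "fh1_black")
}

#' Total FH1-delivered fraction from fluorescence and label ratio
#'
#' Combines the unlabeled fraction `fh1_black = 1 - normalized` with the
#' labeled fraction `fh1_green = fh1_black * pa_label_ratio` (labeled and
#' unlabeled profilin-actin are delivered in proportion to their equilibrium
#' concentrations; see [pa_label_ratio()]) and sums them. Fractions are
#' clamped to `[0, 1]` with a warning; the raw (unclamped) normalized ratio
#' is retained for audit.
#'
#' @param normalized Normalized fluorescence ratio (>= 0). Vectorized.
#' @param pa_label_ratio Ratio of labeled to unlabeled profilin-actin
#'   (>= 0), typically from [pa_label_ratio()] for the reaction condition.
#' @return A data.frame with columns `fh1_black`, `fh1_green`, `fh1_total`,
#'   and `normalized_raw`.
#' @examples
#' fh1_fraction_total(0.4, 0.05)
#' @export
fh1_fraction_total <- function(normalized, pa_label_ratio) {
  stopifnot(is.numeric(pa_label_ratio), length(pa_label_ratio) == 1L ||
              length(pa_label_ratio) == length(normalized))
  if (any(pa_label_ratio < 0)) stop("pa_label_ratio must be >= 0")
  black <- fh1_fraction_black(normalized)
  green <- clamp01(black * pa_label_ratio, "fh1_green")
  total <- clamp01(black + green, "fh1_total")
  data.frame(fh1_black = black, fh1_green = green, fh1_total = total,
             normalized_raw = normalized)
}

#' Per-condition summary of FH1-delivered fractions
#'
#' Computes per-filament FH1-delivered fractions from the fluorescence
#' columns of a filament table and aggregates them per condition (mean, SD,
#' n), mirroring how per-filament fractions are averaged when the
#' dissociation-rate dependence on FH1 delivery is assembled.
#'
#' @param records A filament records data.frame (see
#'   [as_filament_records()]) with `formin_intensity`, `control_intensity`
#'   and `condition_id` columns.
#' @param label_ratios Named numeric vector mapping `condition_id` to the
#'   labeled/unlabeled profilin-actin ratio of that condition.
#' @return A list with `per_filament` (records plus fraction columns) and
#'   `per_condition` (one row per condition: mean, sd, n of `fh1_total`).
#' @export
fh1_condition_summary <- function(records, label_ratios) {
  stopifnot(is.data.frame(records))
  need <- c("condition_id", "formin_intensity", "control_intensity")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    stop("records lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(names(label_ratios)))
    stop("label_ratios must be a named vector keyed by condition_id")
  unknown <- setdiff(unique(records$condition_id), names(label_ratios))
  if (length(unknown) > 0)
    stop("no label ratio supplied for condition(s): ",
         paste(unknown, collapse = ", "))

  norm <- normalized_fluorescence(records$formin_intensity,
                                  records$control_intensity)
  ratio <- unname(label_ratios[as.character(records$condition_id)])
  frac <- fh1_fraction_total(norm, ratio)
  per_filament <- cbind(records, frac)

  agg <- do.call(rbind, lapply(split(frac$fh1_total, records$condition_id),
    function(x) data.frame(mean_fh1_total = mean(x),
                           sd_fh1_total = stats::sd(x), n = length(x))))
  per_condition <- cbind(condition_id = rownames(agg), agg,
                         row.names = NULL)
  list(per_filament = per_filament, per_condition = per_condition)
}
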