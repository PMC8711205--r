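# Reverse-phase HPLC quantification of linker histone H1 stoichiometry.
# Peak areas are trapezoidal integrals of the A214 trace over labelled
# retention-time windows after subtracting a linear baseline anchored at
# the window edges; areas are adjusted per peptide bond so that adjusted
# areas are proportional to molar amounts, and H1/nucleosome ratios
# divide by half the H2B area (two H2B copies per nucleosome).

#' Construct a chromatogram
#'
#' @param time Strictly increasing retention-time grid (minutes).
#' @param a214 Absorbency at 214 nm (mAU) at each time point; finite.
#' @return A data.frame of class `chromatogram` with columns `time`,
#'   `a214`.
#' @export
chromatogram <- function(time, a214) {
  if (length(time) != length(a214))
    stop("time and a214 must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("time grid must be strictly increasing")
  if (any(!is.finite(a214))) stop("a214 values must be finite")
  structure(data.frame(time = time, a214 = a214),
            class = c("chromatogram", "data.frame"))
}

validate_windows <- function(windows) {
  if (any(windows$t_start >= windows$t_end))
    stop("peak windows must satisfy t_start < t_end")
  if (nrow(windows) > 1L) {
    ord <- order(windows$t_start)
    w <- windows[ord, ]
    if (any(w$t_start[-1L] < w$t_end[-nrow(w)]))
      stop("peak windows for distinct labels may not overlap")
  }
  invisible(windows)
}

#' Integrate a chromatogram peak
#'
#' Trapezoidal integral of the A214 signal over `[t_start, t_end]` after
#' subtracting the linear baseline through the signal values at the window
#' edges (edge values are interpolated when they fall between grid
#' points). Negative results are clipped to 0 with a warning. With
#' `baseline = "none"` the raw trapezoidal integral is returned.
#'
#' @param chrom A [chromatogram()].
#' @param t_start,t_end Window bounds (minutes); must lie within the
#'   time grid.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return Peak area in mAU·min.
#' @export
integrate_peak <- function(chrom, t_start, t_end,
                           baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  if (t_start >= t_end) stop("window must satisfy t_start < t_end")
  if (t_start < min(chrom$time) || t_end > max(chrom$time))
    stop("integration window lies outside the chromatogram time grid")
  inner <- chrom$time > t_start & chrom$time < t_end
  ends <- stats::approx(chrom$time, chrom$a214, xout = c(t_start, t_end))$y
  x <- c(t_start, chrom$time[inner], t_end)
  y <- c(ends[1L], chrom$a214[inner], ends[2L])
  area <- pracma::trapz(x, y)
  if (baseline == "linear")
    area <- area - (ends[1L] + ends[2L]) / 2 * (t_end - t_start)
  if (area < 0) {
    warning("negative baseline-subtracted area clipped to 0")
    area <- 0
  }
  area
}

#' Integrate all labelled windows of a chromatogram
#'
#' @param chrom A [chromatogram()].
#' @param windows Data.frame with columns `label`, `t_start`, `t_end`
#'   (non-overlapping).
#' @param baseline Passed to [integrate_peak()].
#' @return Named numeric vector of areas (mAU·min), one per label.
#' @export
integrate_windows <- function(chrom, windows,
                              baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  validate_windows(windows)
  areas <- vapply(seq_len(nrow(windows)), function(i) {
    integrate_peak(chrom, windows$t_start[i], windows$t_end[i], baseline)
  }, numeric(1))
  names(areas) <- windows$label
  areas
}

#' Peptide-bond adjustment of a peak area
#'
#' A214 absorbency scales with the number of peptide bonds, so equal
#' molar amounts of two proteins give raw areas proportional to their
#' bond counts. Dividing by `n_peptide_bonds` (residues - 1) makes areas
#' comparable on a molar scale.
#'
#' @param area Raw peak area (>= 0).
#' @param n_peptide_bonds Positive integer bond count.
#' @return Adjusted area (mAU·min per peptide bond).
#' @export
adjusted_area <- function(area, n_peptide_bonds) {
  if (any(area < 0)) stop("area must be non-negative")
  if (any(n_peptide_bonds <= 0)) stop("n_peptide_bonds must be positive")
  area / n_peptide_bonds
}

#' H1 subtype and total H1 per-nucleosome ratios
#'
#' Ratios divide each peptide-bond-adjusted H1 subtype area by half the
#' adjusted H2B area (a nucleosome carries two H2B copies); the total
#' ratio is the sum over H1 subtypes.
#'
#' @param areas Named vector of adjusted areas including `h2b_label`.
#' @param h1_labels Labels of the H1 subtypes (subset of `names(areas)`).
#' @param h2b_label Label of the H2B peak (default `"H2B"`).
#' @return An `h1_stoichiometry` list: `per_subtype_ratio` (named vector)
#'   and `total_ratio`.
#' @export
h1_nucleosome_ratios <- function(areas, h1_labels = NULL,
                                 h2b_label = "H2B") {
  if (is.null(h1_labels))
    h1_labels <- setdiff(names(areas), h2b_label)
  if (!h2b_label %in% names(areas))
    stop("H2B area is required")
  if (!all(h1_labels %in% names(areas)))
    stop("h1_labels must be a subset of names(areas)")
  h2b_half <- areas[[h2b_label]] / 2
  if (h2b_half <= 0) stop("H2B area must be positive")
  per <- areas[h1_labels] / h2b_half
  structure(list(per_subtype_ratio = per, total_ratio = sum(per)),
            class = "h1_stoichiometry")
}

#' @export
print.h1_stoichiometry <- function(x, ...) {
  cat("H1/nucleosome stoichiometry\n")
  for (s in names(x$per_subtype_ratio))
    cat(sprintf("  %-6s %.4f\n", s, x$per_subtype_ratio[[s]]))
  cat(sprintf("  total  %.4f\n", x$total_ratio))
  invisible(x)
}

#' Percent change between two stoichiometry ratios
#'
#' `100 * (treated - control) / control`; reported both exactly and
#' truncated toward zero to an integer percent (the conventional figure
#' quoted for such ratios).
#'
#' @param ratio_control Control ratio (> 0).
#' @param ratio_treated Treated ratio.
#' @return A list with elements `exact` and `truncated`.
#' @examples
#' percent_change(0.58, 0.67)$truncated  # 15
#' @export
percent_change <- function(ratio_control, ratio_treated) {
  if (ratio_control <= 0) stop("ratio_control must be > 0")
  exact <- 100 * (ratio_treated - ratio_control) / ratio_control
  list(exact = exact, truncated = trunc(exact))
}

#' End-to-end H1 quantification of one chromatogram
#'
#' Integrates every labelled window, applies the peptide-bond adjustment
#' and computes per-subtype and total H1/nucleosome ratios.
#'
#' @param chrom A [chromatogram()].
#' @param windows Window table (`label`, `t_start`, `t_end`).
#' @param subtypes Subtype spec (`label`, `n_peptide_bonds`); must cover
#'   every window label.
#' @param h2b_label Label of the H2B peak (default `"H2B"`).
#' @param baseline Passed to [integrate_peak()].
#' @return An `h1_stoichiometry` object with an `areas` attribute holding
#'   the adjusted areas.
#' @export
quantify_h1 <- function(chrom, windows, subtypes, h2b_label = "H2B",
                        baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  raw <- integrate_windows(chrom, windows, baseline)
  bonds <- subtypes$n_peptide_bonds[match(names(raw), subtypes$label)]
  if (any(is.na(bonds)))
    stop("subtype spec is missing labels: ",
         paste(names(raw)[is.na(bonds)], collapse = ", "))
  adj <- adjusted_area(raw, bonds)
  res <- h1_nucleosome_ratios(adj, h2b_label = h2b_label)
  attr(res, "areas") <- adj
  res
}
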