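# Reference backbone-geometry statistics for the helical families,
# summarizing high-resolution (<= 1.5 A) single-polymer crystal structures.
# Distances were summarized by (single or, for Z-DNA, double) Gaussian
# histogram fits, angles by circular means with resultant lengths; Z-DNA
# distributions are two-component because of its dinucleotide repeat.
.reference_geometry <- local({
  row <- function(kind, quantity, component, n, mean, sd, rbar) {
    tibble::tibble(kind = kind, quantity = quantity, component = component,
                   n = n, mean = mean, sd = sd, Rbar = rbar)
  }
  dplyr::bind_rows(
    # A-DNA
    row("A", "d_c1_3p", 1, 737, 4.77, 0.05, NA),
    row("A", "d_5p_c1", 1, 737, 5.34, 0.08, NA),
    row("A", "ang_c1_p_c1", 1, NA, 65.7, NA, 0.993),
    row("A", "ang_p_c1_p", 1, NA, 73.2, NA, 0.991),
    # B-DNA
    row("B", "d_c1_3p", 1, 1171, 4.29, 0.19, NA),
    row("B", "d_5p_c1", 1, 1171, 5.14, 0.28, NA),
    row("B", "ang_c1_p_c1", 1, NA, 64.6, NA, 0.983),
    row("B", "ang_p_c1_p", 1, NA, 90.6, NA, 0.987),
    # Z-DNA, two components each
    row("Z", "d_c1_3p", 1, 238, 4.52, 0.09, NA),
    row("Z", "d_c1_3p", 2, 238, 4.98, 0.08, NA),
    row("Z", "d_5p_c1", 1, 238, 4.99, 0.10, NA),
    row("Z", "d_5p_c1", 2, 238, 5.62, 0.07, NA),
    row("Z", "ang_c1_p_c1", 1, 151, 76.1, NA, 0.999),
    row("Z", "ang_c1_p_c1", 2, 87, 86.4, NA, 0.999),
    row("Z", "ang_p_c1_p", 1, 155, 74.4, NA, 0.999),
    row("Z", "ang_p_c1_p", 2, 83, 86.7, NA, 0.998),
    # RNA (all conformations pooled)
    row("RNA", "d_c1_3p", 1, 1318, 4.78, 0.05, NA),
    row("RNA", "d_5p_c1", 1, 1318, 5.32, 0.09, NA),
    row("RNA", "ang_c1_p_c1", 1, NA, 67.9, NA, 0.985),
    row("RNA", "ang_p_c1_p", 1, NA, 71.5, NA, 0.993)
  )
})

#' Reference backbone geometry of the helical families
#'
#' Shipped summary constants for the C1'-anchored backbone quantities of
#' A-, B- and Z-form DNA and of RNA: means and standard deviations of the
#' two step distances (`d_c1_3p`: C1' to the 3'-side phosphate; `d_5p_c1`:
#' 5'-side phosphate to C1') from Gaussian histogram fits, and circular
#' means with resultant lengths for the two step angles. Z-DNA rows come in
#' two components per quantity (its backbone alternates between two
#' conformations); `"Z1"`/`"Z2"` select a single component. The values
#' summarize the high-resolution nucleic-acid crystal structures available
#' in mid-2010 and are reference constants, not recomputed by this package.
#'
#' @param kind `"A"`, `"B"`, `"Z"`, `"Z1"`, `"Z2"` or `"RNA"`.
#' @return A tibble with columns `kind`, `quantity`, `component`, `n`,
#'   `mean`, `sd`, `Rbar`.
#' @examples
#' reference_table("B")
#' @export
reference_table <- function(kind = c("A", "B", "Z", "Z1", "Z2", "RNA")) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("A", "B", "Z", "Z1", "Z2", "RNA")) {
    stop("unknown helical family: must be one of A, B, Z, Z1, Z2, RNA",
         call. = FALSE)
  }
  if (kind %in% c("Z1", "Z2")) {
    comp <- as.integer(substr(kind, 2, 2))
    out <- .reference_geometry[.reference_geometry$kind == "Z" &
                               .reference_geometry$component == comp, ]
  } else {
    out <- .reference_geometry[.reference_geometry$kind == kind, ]
  }
  out
}
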