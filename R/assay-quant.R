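#' Quantify smFISH spots per cell
#'
#' Single-molecule FISH quantification: the single-molecule unit intensity
#' is the median integrated intensity of non-transcription-site spots
#' (estimated by a short fixed-point iteration, since transcription sites
#' are themselves defined through the unit); each spot's molecule
#' equivalent is its intensity ratio rounded to the nearest integer.
#' Nuclear spots of three or more molecule equivalents are transcription
#' sites (TS); all other spots contribute their (at least 1) molecule
#' count to the cell's mRNA count.  Cells are classed by the number of TS:
#' `No` (0), `Mono` (1), `Bi` (2); more than two TS is flagged.
#'
#' @param spots data frame with columns `cell` (id), `intensity`
#'   (integrated spot intensity, background-corrected), `nuclear`
#'   (logical).  Optional `y_px`, `x_px` are carried into the TS list.
#' @param min_calibration_spots minimum image-wide spot count required to
#'   calibrate the unit intensity (default 20).
#' @param ts_min_molecules TS definition threshold (default 3).
#' @return List with `unit_intensity` and `cells`, a data frame per cell:
#'   `cell`, `mrna_count`, `n_ts`, `nascent_total`, `allele_class`,
#'   `flagged`; attribute `ts` holds the per-TS table (cell, intensity,
#'   nascent count, raw ratio).
#' @export
quantify_smfish <- function(spots, min_calibration_spots = 20L,
                            ts_min_molecules = 3L) {
  stopifnot(is.data.frame(spots),
            all(c("cell", "intensity", "nuclear") %in% names(spots)))
  if (nrow(spots) < min_calibration_spots)
    stop_txspot("calibration error: %d spots image-wide, need >= %d",
                nrow(spots), min_calibration_spots)
  unit <- median(spots$intensity)
  for (i in 1:3) {  # fixed point: unit from non-TS spots only
    ratio <- spots$intensity / unit
    is_ts <- spots$nuclear & round(ratio) >= ts_min_molecules
    if (all(is_ts)) break
    unit_new <- median(spots$intensity[!is_ts])
    if (abs(unit_new - unit) < 1e-9 * unit) { unit <- unit_new; break }
    unit <- unit_new
  }
  ratio <- spots$intensity / unit
  molecules <- round(ratio)
  is_ts <- spots$nuclear & molecules >= ts_min_molecules

  ts_tab <- data.frame(cell = spots$cell[is_ts],
                       intensity = spots$intensity[is_ts],
                       nascent = molecules[is_ts],
                       ratio = ratio[is_ts])
  if ("y_px" %in% names(spots)) {
    ts_tab$y_px <- spots$y_px[is_ts]; ts_tab$x_px <- spots$x_px[is_ts]
  }

  cells <- lapply(split(seq_len(nrow(spots)), spots$cell), function(idx) {
    ts_i <- idx[is_ts[idx]]
    other <- idx[!is_ts[idx]]
    n_ts <- length(ts_i)
    data.frame(cell = spots$cell[idx[1L]],
               mrna_count = sum(pmax(molecules[other], 1L)),
               n_ts = n_ts,
               nascent_total = sum(molecules[ts_i]),
               allele_class = c("No", "Mono", "Bi")[pmin(n_ts, 2L) + 1L],
               flagged = n_ts > 2L)
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(unit_intensity = unit, cells = cells), ts = ts_tab,
            class = "smfish_result")
}

#' @export
print.smfish_result <- function(x, ...) {
  cat(sprintf("smFISH quantification: %d cells, unit intensity %.4g\n",
              nrow(x$cells), x$unit_intensity))
  print(table(x$cells$allele_class))
  invisible(x)
}

#' ChIP-qPCR percent input and fold enrichment
#'
#' Percent input from qPCR Ct values:
#' `%input = 2^((Ct_input - input_adjust) - Ct_sample) * 100`, where
#' `input_adjust` (default 5.64) corrects the saved input fraction and its
#' dilution to the IP scale.  When a reference primer pair is supplied,
#' fold enrichment is the sample's percent input divided by the
#' reference's.
#'
#' @param ct_input input-chromatin Ct value(s).
#' @param ct_sample immunoprecipitated-sample Ct value(s), same length.
#' @param ct_reference_pair optional `c(ct_input_ref, ct_sample_ref)` for
#'   the reference locus.
#' @param input_adjust dilution/fraction correction in Ct units.
#' @return Data frame `percent_input` (+ `fold_enrichment` when a
#'   reference is given).
#' @examples
#' chip_percent_input(20, 25)  # ~0.0627 percent
#' @export
chip_percent_input <- function(ct_input, ct_sample,
                               ct_reference_pair = NULL,
                               input_adjust = 5.64) {
  if (!all(is.finite(ct_input), is.finite(ct_sample)))
    stop_txspot("Ct values must be finite")
  pct <- 2^((ct_input - input_adjust) - ct_sample) * 100
  out <- data.frame(percent_input = pct)
  if (!is.null(ct_reference_pair)) {
    ref <- 2^((ct_reference_pair[1L] - input_adjust) -
                ct_reference_pair[2L]) * 100
    out$fold_enrichment <- pct / ref
  }
  out
}
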