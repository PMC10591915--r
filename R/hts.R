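#' Positive/negative control signature of a screening plate
#'
#' Summarises the control wells of a plate into the reference the binding
#' score needs: mean 350/480 nm signals of the positive-control wells
#' (full displacement of the retinoid) and of the negative-control wells
#' (holo protein plus vehicle). The reference is only valid if the
#' positive control actually changes the signal at both wavelengths.
#'
#' @param plate a `plate_table` data frame (see [simulate_plate()] /
#'   [read_plate_csv()]), or explicit scalars via the other arguments.
#' @param pc350,pc480,nc350,nc480 scalar overrides; when `plate` is NULL
#'   all four must be given.
#' @return An object of class `screen_reference`.
#' @export
screen_reference <- function(plate = NULL, pc350 = NULL, pc480 = NULL,
                             nc350 = NULL, nc480 = NULL) {
  if (!is.null(plate)) {
    pos <- plate[plate$role == "pos_ctrl", , drop = FALSE]
    neg <- plate[plate$role == "neg_ctrl", , drop = FALSE]
    if (nrow(pos) == 0 || nrow(neg) == 0)
      stop("plate must contain pos_ctrl and neg_ctrl wells")
    pc350 <- mean(pos$f350); pc480 <- mean(pos$f480)
    nc350 <- mean(neg$f350); nc480 <- mean(neg$f480)
  }
  vals <- c(pc350, pc480, nc350, nc480)
  if (length(vals) != 4 || any(!is.finite(vals)) || any(vals < 0))
    stop("reference signals must be four finite non-negative numbers")
  if (pc350 == nc350 || pc480 == nc480)
    stop("reference has zero signal change at one wavelength")
  structure(list(pc350 = pc350, pc480 = pc480,
                 nc350 = nc350, nc480 = nc480),
            class = "screen_reference")
}

#' Binding score of a compound well
#'
#' Scores how closely a well's background-subtracted fluorescence changes
#' at 350 and 480 nm reproduce the positive-control signature. With
#' `r350 = (f350 - nc350) / (pc350 - nc350)` and likewise `r480` (signed,
#' so the characteristic 480 nm decrease gives a positive ratio), the
#' default score is
#'
#'   `score = 2 - |1 - r350| - |1 - r480|`
#'
#' which is maximal (2) when both changes equal the control's, and
#' penalises no-change and overshoot symmetrically; a combined deviation
#' of 0.5 lands exactly on the 1.5 hit threshold. The score depends only
#' on the two ratios, so it is invariant under a common rescaling of all
#' plate signals. An alternative scoring function can be supplied via
#' `score_fn(r350, r480)`.
#'
#' @param f350,f480 well signals (a.u.), vectorised.
#' @param ref a [screen_reference()].
#' @param score_fn optional function of the two ratios replacing the
#'   default score.
#' @return numeric score(s).
#' @export
binding_score <- function(f350, f480, ref, score_fn = NULL) {
  stopifnot(inherits(ref, "screen_reference"))
  r350 <- (f350 - ref$nc350) / (ref$pc350 - ref$nc350)
  r480 <- (f480 - ref$nc480) / (ref$pc480 - ref$nc480)
  if (is.null(score_fn)) {
    2 - abs(1 - r350) - abs(1 - r480)
  } else {
    score_fn(r350, r480)
  }
}

#' Optical-artifact exclusion
#'
#' Wells flagged for UV/vis absorbance or autofluorescence are excluded
#' from hit calling regardless of score, with the reason recorded.
#'
#' @param absorbance_flag,autofluorescence_flag logical vectors.
#' @return data frame with `excluded` and `exclusion_reason` (NA when not
#'   excluded; "absorbance" takes precedence when both flags are set).
#' @export
artifact_filter <- function(absorbance_flag, autofluorescence_flag) {
  excluded <- absorbance_flag | autofluorescence_flag
  reason <- rep(NA_character_, length(excluded))
  reason[autofluorescence_flag] <- "autofluorescence"
  reason[absorbance_flag] <- "absorbance"
  data.frame(excluded = excluded, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Score a plate and call hits
#'
#' Applies [binding_score()] to every compound well of a plate against the
#' plate's own control signature, applies [artifact_filter()], and calls
#' hits at `score >= threshold` among non-excluded wells. Results are
#' ordered by descending score, ties broken by well id.
#'
#' @param plate a `plate_table` data frame.
#' @param threshold hit threshold on the score (default 1.5; the boundary
#'   is inclusive).
#' @param ref optional [screen_reference()]; computed from the plate's
#'   control wells when omitted.
#' @param score_fn optional replacement scoring function, passed to
#'   [binding_score()].
#' @return A `screen_result` data frame: `well_id`, `score`, `excluded`,
#'   `exclusion_reason`, `is_hit`, ordered by descending score then
#'   `well_id`; attribute `threshold`.
#' @export
screen_plate <- function(plate, threshold = 1.5, ref = NULL,
                         score_fn = NULL) {
  if (is.null(ref)) ref <- screen_reference(plate)
  cmp <- plate[plate$role == "compound", , drop = FALSE]
  score <- binding_score(cmp$f350, cmp$f480, ref, score_fn = score_fn)
  filt <- artifact_filter(cmp$absorbance_flag, cmp$autofluorescence_flag)
  out <- data.frame(well_id = cmp$well_id, score = score,
                    excluded = filt$excluded,
                    exclusion_reason = filt$exclusion_reason,
                    is_hit = !filt$excluded & score >= threshold,
                    stringsAsFactors = FALSE)
  if ("true_class" %in% names(cmp)) out$true_class <- cmp$true_class
  out <- out[order(-out$score, out$well_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "reference") <- ref
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Hit list of a screened plate
#'
#' @param result a `screen_result` from [screen_plate()].
#' @return character vector of hit well ids, descending score order.
#' @export
call_hits <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  result$well_id[result$is_hit]
}
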