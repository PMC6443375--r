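# Spillover compensation. Model: observed = true %*% S over the
# detector columns (the FCS $SPILLOVER convention), so compensation is
# a right-multiplication by solve(S). Applied on the linearized raw
# scale, before display transforms, per the Gating-ML processing order.

#' Parse an FCS $SPILLOVER / $SPILL keyword value
#'
#' The keyword is `"k,det1,...,detk,v11,...,vkk"` with the k x k
#' coefficients row-major. Matrices stored with a non-unit diagonal are
#' row-scaled so the diagonal becomes 1.
#'
#' @param text the keyword value.
#' @return A [SpilloverMatrix-class].
#' @examples
#' parseSpilloverKeyword("2,FL1,FL2,1,0.1,0.05,1")
#' @export
parseSpilloverKeyword <- function(text) {
  tok <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  k <- suppressWarnings(as.integer(tok[1]))
  if (is.na(k) || k < 1 || length(tok) != 1 + k + k * k)
    cytoStop("MALFORMED_SPILLOVER", sprintf(
      "$SPILLOVER has %d tokens, expected 1 + k + k^2 (k = %s)",
      length(tok), tok[1]))
  detectors <- tok[2:(1 + k)]
  vals <- suppressWarnings(as.numeric(tok[(2 + k):length(tok)]))
  if (anyNA(vals))
    cytoStop("MALFORMED_SPILLOVER", "non-numeric spillover coefficient")
  S <- matrix(vals, nrow = k, ncol = k, byrow = TRUE)
  spilloverMatrix(detectors, S)
}

#' Serialize a spillover matrix as an FCS $SPILLOVER keyword value
#' @param sm a [SpilloverMatrix-class].
#' @return The keyword string.
#' @export
buildSpilloverKeyword <- function(sm) {
  k <- length(sm@detectors)
  paste(c(k, sm@detectors, fmtNum(as.vector(t(sm@S)))), collapse = ",")
}

identitySpillover <- function(detectors)
  spilloverMatrix(detectors, diag(length(detectors)))

isIdentitySpillover <- function(sm)
  max(abs(sm@S - diag(length(sm@detectors)))) == 0

#' Apply spillover compensation to an event matrix
#'
#' Only the detector columns change; all other columns are returned
#' bit-identical. Applying the spillover (`X %*% S`) and then
#' compensating recovers the input to ~1e-9 relative for
#' well-conditioned matrices.
#'
#' @param events numeric event matrix with named columns (or supply
#'   `channels`).
#' @param sm a [SpilloverMatrix-class].
#' @param channels channel names for the columns of `events`.
#' @return The compensated matrix.
#' @export
compensate <- function(events, sm, channels = colnames(events)) {
  if (is.null(channels))
    cytoStop("UNRESOLVED_CHANNEL", "event matrix has no channel names")
  idx <- match(sm@detectors, channels)
  if (anyNA(idx))
    cytoStop("UNRESOLVED_CHANNEL", paste0(
      "spillover detector(s) not among sample channels: ",
      paste(sm@detectors[is.na(idx)], collapse = ", ")))
  if (!is.finite(rcond(sm@S)) || rcond(sm@S) < 1e-12)
    cytoStop("SINGULAR_MATRIX", "spillover matrix is singular or near-singular")
  Sinv <- solve(sm@S)
  events[, idx] <- events[, idx, drop = FALSE] %*% Sinv
  events
}

#' Apply spillover (the forward model observed = true %*% S)
#' @inheritParams compensate
#' @return The spilled (observed) matrix.
#' @export
applySpillover <- function(events, sm, channels = colnames(events)) {
  idx <- match(sm@detectors, channels)
  if (anyNA(idx))
    cytoStop("UNRESOLVED_CHANNEL", paste0(
      "spillover detector(s) not among sample channels: ",
      paste(sm@detectors[is.na(idx)], collapse = ", ")))
  events[, idx] <- events[, idx, drop = FALSE] %*% sm@S
  events
}

#' Select the compensation matrix for a gate evaluation
#'
#' Precedence mirrors the automatic detection of analysis-time custom
#' matrices: an explicit gate reference wins; otherwise (`"auto"`) a
#' workspace matrix registered under the sample's id (a per-sample
#' custom matrix, e.g. from a FlowJo workspace) is chosen over the FCS
#' $SPILLOVER/$SPILL keyword, which is chosen over identity.
#' `"uncompensated"` always yields identity. The selection and its
#' provenance are logged at INFO.
#'
#' @param sample a [CytoSample-class].
#' @param ws the owning [Workspace-class].
#' @param gateRef the gate dimension's compensation reference.
#' @return A [SpilloverMatrix-class] (identity when none applies).
#' @export
selectCompensation <- function(sample, ws, gateRef = "auto") {
  chans <- channelNames(sample)
  if (identical(gateRef, "uncompensated")) {
    cytoLog("DEBUG", "compensation: uncompensated by gate reference")
    return(identitySpillover(chans))
  }
  if (!identical(gateRef, "auto")) {
    sm <- ws@compensations[[gateRef]]
    if (is.null(sm))
      cytoStop("UNRESOLVED_COMPENSATION",
               paste0("no compensation matrix registered as '", gateRef, "'"))
    cytoLog("INFO", "compensation for '", sample@sampleId,
            "': explicit gate reference '", gateRef, "'")
    return(sm)
  }
  sm <- ws@compensations[[sample@sampleId]]
  if (!is.null(sm)) {
    cytoLog("INFO", "compensation for '", sample@sampleId,
            "': workspace custom matrix (auto-selected)")
    return(sm)
  }
  kw <- keywords(sample)
  key <- intersect(c("$SPILLOVER", "$SPILL", "SPILL"), names(kw))
  if (length(key)) {
    cytoLog("INFO", "compensation for '", sample@sampleId,
            "': FCS ", key[1], " keyword")
    return(parseSpilloverKeyword(kw[[key[1]]]))
  }
  cytoLog("INFO", "compensation for '", sample@sampleId,
          "': none found, identity")
  identitySpillover(chans)
}
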