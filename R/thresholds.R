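#' Construct the caller thresholds
#'
#' Returns an [ErvThresholds] object holding every numeric cutoff of the two
#' callers, initialised to the published defaults; any of them can be
#' overridden by name.
#'
#' @param ... named overrides of [ErvThresholds] slots, e.g.
#'   \code{ervThresholds(minInformative = 6)}.
#' @return An [ErvThresholds] object.
#' @examples
#' th <- ervThresholds()
#' th@minInformative
#' ervThresholds(insertSizeMax = 800)@insertSizeMax
#' @export
ervThresholds <- function(...) {
  args <- list(...)
  obj <- new("ErvThresholds")
  if (length(args)) {
    bad <- setdiff(names(args), slotNames(obj))
    if (length(bad) || is.null(names(args)) || any(!nzchar(names(args))))
      stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
    for (nm in names(args)) slot(obj, nm) <- as.numeric(args[[nm]])
    validObject(obj)
  }
  obj
}
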