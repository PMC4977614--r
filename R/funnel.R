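# The filter funnel: ordered per-stage, per-region-class survivor counts.

new_funnel <- function() {
  structure(list(stages = character(0),
                 counts = list(),
                 intolerance = NULL),
            class = "filter_funnel")
}

funnel_add <- function(funnel, stage, regions) {
  cnt <- table(factor(regions, levels = REGION_LEVELS))
  funnel$stages <- c(funnel$stages, stage)
  funnel$counts[[stage]] <- as.integer(cnt)
  funnel
}

#' Funnel as a stage-by-region count table
#'
#' @param x a `filter_funnel` as produced by [run_pipeline()]
#' @param ... ignored
#' @return data.frame: one row per stage (in execution order), one column
#'   per region class, plus a `total` column
#' @export
as.data.frame.filter_funnel <- function(x, ...) {
  if (length(x$stages) == 0L) {
    out <- as.data.frame(matrix(integer(0), 0, length(REGION_LEVELS) + 1L))
    names(out) <- c(REGION_LEVELS, "total")
    return(cbind(data.frame(stage = character(0)), out))
  }
  m <- do.call(rbind, x$counts[x$stages])
  colnames(m) <- REGION_LEVELS
  data.frame(stage = x$stages, m, total = rowSums(m),
             row.names = NULL, check.names = FALSE)
}

#' Validate funnel invariants
#'
#' Counts must be non-negative and non-increasing along the stage order for
#' every region class.
#'
#' @param funnel a `filter_funnel`
#' @return `TRUE` invisibly; errors otherwise
#' @export
validate_funnel <- function(funnel) {
  df <- as.data.frame(funnel)
  m <- as.matrix(df[REGION_LEVELS])
  if (any(m < 0)) stop("funnel counts must be non-negative")
  if (nrow(m) > 1L && any(diff(m) > 0))
    stop("funnel counts increase along the stage order")
  invisible(TRUE)
}

#' Human-readable funnel summary
#'
#' One row per stage, one column per region class. When the intolerance
#' sub-stage ran in flag mode, coding columns of the final row show both
#' counts as `with (without)` — the with-intolerance count in front, the
#' parenthetical giving the count if intolerance is not considered.
#'
#' @param funnel a `filter_funnel`
#' @return data.frame of character cells
#' @export
summarize_funnel <- function(funnel) {
  df <- as.data.frame(funnel)
  if (nrow(df) == 0L) return(df)
  out <- df
  for (cl in c(REGION_LEVELS, "total")) out[[cl]] <- as.character(df[[cl]])
  it <- funnel$intolerance
  if (!is.null(it)) {
    last <- nrow(out)
    for (cl in names(it$with)) {
      if (!cl %in% names(out)) next
      out[[cl]][last] <- sprintf("%d (%d)", it$with[[cl]], it$without[[cl]])
    }
  }
  out
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("filter funnel (", length(x$stages), " stages)\n", sep = "")
  print(summarize_funnel(x), row.names = FALSE)
  invisible(x)
}
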