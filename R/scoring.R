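#' Linear discriminant scoring model
#'
#' A five-epoch sleep/wake discriminant for 2-min activity counts.  The
#' score of an epoch is the dot product of the coefficient vector
#' (a_-2, a_-1, a, a_+1, a_+2) with the activity counts at 4 and 2 min
#' before, at, and 2 and 4 min after the epoch; a score at or above the
#' threshold means wake, below means sleep.  There is no intercept: the
#' threshold carries the boundary.
#'
#' @param coefficients Numeric vector of exactly 5 finite coefficients, in
#'   window order (x_-2, x_-1, x, x_+1, x_+2); readers must not reorder.
#' @param threshold Finite decision threshold (default 1).
#' @param label Short name recorded in outputs.
#' @return An object of class \code{"discriminant_model"}.
#' @seealso [child_fs760()], [discriminant_score()], [score_series()]
#' @export
discriminant_model <- function(coefficients, threshold = 1, label = "custom") {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 5L)
    stop(sprintf("a discriminant model needs exactly 5 coefficients, got %d",
                 length(coefficients)), call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(list(coefficients = coefficients, threshold = as.numeric(threshold),
                 label = as.character(label)[1]),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("discriminant model '%s'\n  z = %s\n  wake when z >= %g\n",
              x$label,
              paste(sprintf("%.6f x%+d", x$coefficients, -2:2), collapse = " + "),
              x$threshold))
  invisible(x)
}

#' Built-in child scoring model for the waist-worn FS-760
#'
#' The published five-epoch discriminant for school-aged children wearing
#' the FS-760 on the waist:
#' z = 0.108294 x_-2 + 0.147294 x_-1 + 0.230126 x + 0.099353 x_+1 +
#' 0.059580 x_+2, with wake scored when z >= 1.
#'
#' @return A [discriminant_model()] with label \code{"child_fs760"}.
#' @export
child_fs760 <- function() {
  discriminant_model(c(0.108294, 0.147294, 0.230126, 0.099353, 0.059580),
                     threshold = 1, label = "child_fs760")
}

#' Discriminant score of one five-epoch window
#'
#' @param window Numeric vector of 5 activity values
#'   (x_-2, x_-1, x, x_+1, x_+2).
#' @param model A [discriminant_model()].
#' @return The score z, an exact dot product with no intercept.
#' @examples
#' discriminant_score(c(0, 0, 5, 0, 0), child_fs760())  # 1.15063 -> wake
#' @export
discriminant_score <- function(window, model) {
  stopifnot(inherits(model, "discriminant_model"))
  window <- as.numeric(window)
  if (length(window) != 5L)
    stop(sprintf("scoring window must hold 5 values, got %d", length(window)),
         call. = FALSE)
  if (any(!is.finite(window)))
    stop("scoring window must be finite", call. = FALSE)
  sum(model$coefficients * window)
}

#' Classify a score as sleep or wake
#'
#' @param z Finite discriminant score (vectorized).
#' @param model A [discriminant_model()] supplying the threshold.
#' @return \code{"W"} where \code{z >= threshold}, else \code{"S"}.
#' @export
classify_sw <- function(z, model) {
  stopifnot(inherits(model, "discriminant_model"))
  if (any(!is.finite(z))) stop("score must be finite", call. = FALSE)
  ifelse(z >= model$threshold, "W", "S")
}

edge_window <- function(counts, i, policy) {
  n <- length(counts)
  idx <- (i - 2L):(i + 2L)
  if (policy == "zero") {
    w <- numeric(5)
    ok <- idx >= 1L & idx <= n
    w[ok] <- counts[idx[ok]]
    w
  } else {
    counts[pmin(pmax(idx, 1L), n)]
  }
}

#' Score an activity series epoch by epoch
#'
#' Slides the five-epoch window over the series and classifies every epoch.
#' The first and last two epochs lack full context; the \code{edge} policy
#' decides how their missing neighbours are filled: \code{"zero"} (default)
#' treats them as zero activity (deterministically biasing edges toward
#' sleep), \code{"extend"} replicates the nearest recorded count.
#'
#' @param act An [activity_series()] or a bare numeric vector of counts.
#' @param model A [discriminant_model()]; default [child_fs760()].
#' @param edge Edge policy, \code{"zero"} or \code{"extend"}.
#' @return A data frame of class \code{"sw_series"} with one row per input
#'   epoch: \code{epoch_index} (0-based), \code{count}, \code{z},
#'   \code{label} (\code{"S"}/\code{"W"}).  The model label, coefficients,
#'   threshold and edge policy are stored as attributes.
#' @export
score_series <- function(act, model = child_fs760(),
                         edge = c("zero", "extend")) {
  edge <- match.arg(edge)
  stopifnot(inherits(model, "discriminant_model"))
  counts <- if (inherits(act, "activity_series")) act$counts else
    as.numeric(act)
  if (length(counts) < 1L) stop("empty activity series", call. = FALSE)
  if (any(!is.finite(counts)))
    stop("activity counts must be finite", call. = FALSE)
  z <- vapply(seq_along(counts), function(i)
    sum(model$coefficients * edge_window(counts, i, edge)), numeric(1))
  out <- data.frame(epoch_index = seq_along(counts) - 1L,
                    count = counts,
                    z = z,
                    label = classify_sw(z, model),
                    stringsAsFactors = FALSE)
  attr(out, "model_label") <- model$label
  attr(out, "coefficients") <- model$coefficients
  attr(out, "threshold") <- model$threshold
  attr(out, "edge_policy") <- edge
  class(out) <- c("sw_series", "data.frame")
  out
}
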