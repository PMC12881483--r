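#' Payoff grids of the six primary SVO slider items
#'
#' The standard slider instrument's six primary items, each offering nine
#' joint (self, other) allocations.  These grids are constants of the
#' instrument itself.
#'
#' @return List of six matrices (9 x 2, columns `self`, `other`).
#' @export
svo_items <- function() {
  items <- list(
    cbind(self = c(85, 85, 85, 85, 85, 85, 85, 85, 85),
          other = c(85, 76, 68, 59, 50, 41, 33, 24, 15)),
    cbind(self = c(85, 87, 89, 91, 93, 94, 96, 98, 100),
          other = c(15, 19, 24, 28, 33, 37, 41, 46, 50)),
    cbind(self = c(50, 54, 59, 63, 68, 72, 76, 81, 85),
          other = c(100, 98, 96, 94, 93, 91, 89, 87, 85)),
    cbind(self = c(50, 54, 59, 63, 68, 72, 76, 81, 85),
          other = c(100, 89, 79, 68, 58, 47, 36, 26, 15)),
    cbind(self = c(100, 94, 88, 81, 75, 69, 63, 56, 50),
          other = c(50, 56, 63, 69, 75, 81, 88, 94, 100)),
    cbind(self = c(100, 98, 96, 94, 93, 91, 89, 87, 85),
          other = c(50, 54, 59, 63, 68, 72, 76, 81, 85)))
  items
}

#' SVO angle from six slider allocations
#'
#' The angle is computed from the *means* of the six chosen allocations
#' (not from per-item angles), following the standard slider convention
#' with both anchors at 50:
#' `angle = atan((mean_other - 50) / (mean_self - 50))` in degrees.
#' Larger angles are more prosocial; admissible primary-item responses
#' yield angles between -16.26 and 61.39 degrees.  When the mean self
#' payoff equals 50 the angle is +-90 degrees by the sign of the
#' numerator (0 when both means are 50).
#'
#' @param self_payoffs,other_payoffs The six chosen payoffs for self and
#'   other (any equal length >= 1 is accepted).
#' @return Angle in degrees.
#' @export
svo_angle <- function(self_payoffs, other_payoffs) {
  stopifnot(length(self_payoffs) == length(other_payoffs),
            length(self_payoffs) >= 1)
  ms <- mean(self_payoffs) - 50
  mo <- mean(other_payoffs) - 50
  if (ms == 0) {
    if (mo == 0) return(0)
    return(sign(mo) * 90)
  }
  atan(mo / ms) * 180 / pi
}

#' Score an SVO profile given chosen option indices
#'
#' @param choices Integer vector of length 6 with the chosen option (1-9)
#'   for each primary item.
#' @return List with the chosen `self`/`other` payoffs, their means and
#'   the `angle` in degrees.
#' @export
score_svo <- function(choices) {
  stopifnot(length(choices) == 6, all(choices %in% 1:9))
  items <- svo_items()
  self <- sapply(1:6, function(i) items[[i]][choices[i], "self"])
  other <- sapply(1:6, function(i) items[[i]][choices[i], "other"])
  list(self = self, other = other, mean_self = mean(self),
       mean_other = mean(other), angle = svo_angle(self, other))
}
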