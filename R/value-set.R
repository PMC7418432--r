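EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Read an EQ-5D-3L value set from a YAML file
#'
#' A value set (tariff) converts a 5-digit EQ-5D-3L health state into a
#' utility anchored at 1 (full health) and 0 (dead). The file supplies a
#' constant decrement applied once if any dimension is above level 1,
#' level-2 and level-3 decrements for each of the five dimensions, and an
#' "N3" decrement applied once if any dimension is at level 3.
#'
#' @param path path to a YAML value-set file; see
#'   `system.file("extdata", "eq5d3l_uk_tto.yaml", package = "trialcea")`
#'   for the shipped UK time-trade-off tariff used by default.
#' @return an object of class `eq5d_value_set`.
#' @seealso [score_eq5d()], [default_value_set()]
#' @export
read_value_set <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("constant", "n3", "dimensions"))
    if (is.null(raw[[f]])) stopf("value-set file lacks field '%s'", f)
  dims <- raw$dimensions
  missing_dims <- setdiff(EQ5D_DIMENSIONS, names(dims))
  if (length(missing_dims))
    stopf("value-set file lacks dimension(s): %s",
          paste(missing_dims, collapse = ", "))
  dec <- rbind(
    level2 = vapply(EQ5D_DIMENSIONS, function(d) dims[[d]]$level2, 0),
    level3 = vapply(EQ5D_DIMENSIONS, function(d) dims[[d]]$level3, 0)
  )
  vs <- structure(
    list(name = raw$name %||% "custom",
         constant = raw$constant, n3 = raw$n3, decrements = dec),
    class = "eq5d_value_set"
  )
  if (any(c(vs$constant, vs$n3, dec) < 0))
    stopf("value-set decrements must all be non-negative")
  vs
}

#' Default EQ-5D-3L value set (UK TTO tariff)
#'
#' @return the shipped UK time-trade-off value set, under which the worst
#'   state 33333 scores -0.594.
#' @export
default_value_set <- function() {
  read_value_set(system.file("extdata", "eq5d3l_uk_tto.yaml",
                             package = "trialcea"))
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set '", x$name, "'\n", sep = "")
  cat("  constant:", x$constant, " N3:", x$n3, "\n")
  cat("  worst state (33333) value:",
      1 - x$constant - sum(x$decrements["level3", ]) - x$n3, "\n")
  invisible(x)
}

parse_eq5d_states <- function(states) {
  if (is.numeric(states)) states <- sprintf("%05d", states)
  states <- as.character(states)
  bad <- !grepl("^[123]{5}$", states)
  if (any(bad))
    stopf("malformed EQ-5D-3L state(s): %s (each of 5 digits must be 1-3)",
          paste(unique(states[bad]), collapse = ", "))
  m <- matrix(as.integer(unlist(strsplit(states, ""))),
              ncol = 5, byrow = TRUE)
  colnames(m) <- EQ5D_DIMENSIONS
  m
}

#' Score EQ-5D-3L health states into utilities
#'
#' Applies the additive decrement model: utility = 1, minus the constant if
#' any dimension exceeds level 1, minus the applicable per-dimension level-2
#' or level-3 decrements, minus the N3 term if any dimension is at level 3.
#' Full health (11111) scores exactly 1.
#'
#' @param states character or numeric vector of 5-digit states, each digit in
#'   1-3 (e.g. `"21123"`), or a 5-column integer matrix.
#' @param value_set an `eq5d_value_set`; defaults to the shipped UK tariff.
#' @return numeric vector of utilities.
#' @examples
#' score_eq5d(c("11111", "33333"))
#' @export
score_eq5d <- function(states, value_set = default_value_set()) {
  m <- if (is.matrix(states)) {
    if (ncol(states) != 5 || !all(states %in% 1:3))
      stopf("state matrix must have 5 columns with entries in 1-3")
    states
  } else parse_eq5d_states(states)
  dec2 <- value_set$decrements["level2", ]
  dec3 <- value_set$decrements["level3", ]
  any2plus <- rowSums(m > 1) > 0
  any3 <- rowSums(m == 3) > 0
  per_dim <- (m == 2) %*% dec2 + (m == 3) %*% dec3
  as.numeric(1 - any2plus * value_set$constant - per_dim - any3 * value_set$n3)
}

#' Enumerate all 243 EQ-5D-3L states
#'
#' @return character vector of all 3^5 five-digit profiles, "11111" first.
#' @export
eq5d_states <- function() {
  g <- expand.grid(rep(list(1:3), 5))[, 5:1]
  apply(g, 1, paste0, collapse = "")
}
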