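#' @importFrom stats runif rnorm approxfun optim quantile setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stochastically round a non-negative real count to an integer
#'
#' Rounds `x` down and adds one with probability equal to the fractional
#' part, so the expected value of the result equals `x`. Used when real-valued
#' aggregate flows (persons) must become whole agents.
#'
#' @param x numeric vector of non-negative values.
#' @param u uniform(0,1) draws of the same length.
#' @return integer-valued numeric vector.
#' @keywords internal
stochastic_round <- function(x, u) {
  f <- floor(x)
  f + as.numeric(u < (x - f))
}

## ---- derived random streams -------------------------------------------------
##
## Every random draw in the engine comes from a substream identified by
## (master seed, purpose, step index). Substreams are realised by deriving a
## scalar seed and drawing with R's Mersenne-Twister, with draws indexed by
## agent id so results do not depend on the iteration order of any internal
## collection. This is what makes scenario pairs sharing a master seed differ
## only in the draws a policy change logically touches.

PURPOSE <- c(
  init_age = 1L, phenotype = 2L, height = 3L, bmi_init = 4L, fam_hist = 5L,
  bud = 6L, mortality = 7L, bmi_noise = 8L, conception = 9L,
  participation = 10L, sex = 11L, gwg = 12L, adverse = 13L, uptake = 14L,
  risk_count = 15L, preg_jitter = 16L, replicate = 17L, calibrate = 18L
)

stream_seed <- function(master, purpose, step = 0L) {
  s <- (as.numeric(master) %% 2147483647) * 48271 +
    as.numeric(purpose) * 30323 + as.numeric(step) * 7559
  as.integer(s %% 2147483587) + 1L
}

draw_unif <- function(master, purpose, step, n) {
  if (n == 0L) return(numeric(0))
  set.seed(stream_seed(master, PURPOSE[[purpose]], step))
  runif(n)
}

draw_norm <- function(master, purpose, step, n) {
  if (n == 0L) return(numeric(0))
  set.seed(stream_seed(master, PURPOSE[[purpose]], step))
  rnorm(n)
}

#' Derive replicate seeds from a master seed
#'
#' @param master integer master seed.
#' @param n number of replicate seeds.
#' @return integer vector of length `n`, deterministic in `master`.
#' @export
replicate_seeds <- function(master, n) {
  vapply(seq_len(n), function(i) stream_seed(master, PURPOSE[["replicate"]], i),
         integer(1))
}

## assign into a nested list by a character path; a trailing all-digit
## component indexes into a vector, e.g. c("diagnostics","thresholds","2")
set_by_path <- function(lst, path, value) {
  if (length(path) == 1L) {
    lst[[path]] <- value
    return(lst)
  }
  key <- path[1L]
  rest <- path[-1L]
  if (length(rest) == 1L && grepl("^[0-9]+$", rest)) {
    lst[[key]][as.integer(rest)] <- value
  } else {
    lst[[key]] <- set_by_path(lst[[key]] %||% list(), rest, value)
  }
  lst
}

get_by_path <- function(lst, path) {
  for (key in path) {
    if (grepl("^[0-9]+$", key)) lst <- lst[[as.integer(key)]] else lst <- lst[[key]]
  }
  lst
}

#' @useDynLib dipsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
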