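#' Sleep-stage and subject-group vocabularies
#'
#' Six-class sleep staging on 30-s epochs distinguishes wakefulness (W), the
#' four NREM sub-stages S1--S4 and REM sleep. [stage_levels()] returns the
#' canonical class order used throughout the package (confusion matrices,
#' class scores, tie-breaking). [group_levels()] returns the subject groups of
#' the CAP sleep database cohort: healthy plus seven sleep disorders.
#'
#' @return Character vector of levels.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() {
  c("W", "S1", "S2", "S3", "S4", "REM")
}

#' @rdname stage_levels
#' @export
group_levels <- function() {
  c("healthy", "insomnia", "bruxism", "narcolepsy", "NFLE", "PLM", "RBD", "SDB")
}

#' Normalize a stage label
#'
#' Maps scorer dialects onto the six canonical labels: "R" and "REM" both mean
#' REM, "W"/"Wake"/"WAKE" mean W, "S1".."S4" pass through. Anything else
#' (e.g. movement time "MT") returns NA.
#'
#' @param x character vector of raw labels.
#' @return character vector with entries from [stage_levels()] or NA.
#' @export
normalize_stage <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(up))
  out[up %in% c("W", "WAKE")] <- "W"
  out[up %in% c("S1", "S2", "S3", "S4")] <- up[up %in% c("S1", "S2", "S3", "S4")]
  out[up %in% c("R", "REM")] <- "REM"
  out
}

stage_factor <- function(x) {
  factor(as.character(x), levels = stage_levels())
}

# Run expr with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit stream seed derived from a master seed and a key string,
# so per-epoch streams are independent of generation order.
derive_seed <- function(master, ...) {
  key <- paste(c(format(as.integer(master)), as.character(list(...))), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647L
  as.integer((h + as.integer(master)) %% 2147483647L)
}
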