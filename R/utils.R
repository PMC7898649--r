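# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
# All stochastic entry points take an explicit seed; no function leaves the
# caller's RNG state altered.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Row-wise min/max over a numeric matrix without apply() overhead.
row_min <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = FALSE))
row_max <- function(m) do.call(pmax, c(as.data.frame(m), na.rm = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_levels <- function() c("early", "mid", "late")
caste_levels <- function() c("Q", "W")

check_metadata <- function(samples) {
  req <- c("sample_id", "stage", "caste", "replicate")
  missing <- setdiff(req, names(samples))
  if (length(missing)) {
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id in metadata")
  bad <- setdiff(unique(samples$stage), stage_levels())
  if (length(bad)) stop("unknown stage value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$caste), caste_levels())
  if (length(bad)) stop("unknown caste value(s): ", paste(bad, collapse = ", "))
  invisible(samples)
}
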