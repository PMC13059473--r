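#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a run seed and a tag
#'
#' Every source of randomness in the package draws from a seed derived from
#' the single run seed plus a purpose tag, so that independent stages
#' (allele generation, noise draws, fold shuffling, ...) are decoupled but
#' jointly reproducible. The result is always a valid 32-bit R integer.
#'
#' @param seed integer run seed
#' @param tag character tag naming the consumer
#' @return integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

#' Stop with a classed condition
#' @keywords internal
cmhs_stop <- function(msg, class) {
  stop(structure(class = c(class, "cmhs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deep-merge two configuration lists
#'
#' Values in `override` replace values in `base`; nested lists are merged
#' recursively. Unknown keys in `override` (absent from `base`) raise a
#' validation error so that typos in config files fail loudly.
#' @param base default config (defines the schema)
#' @param override user values
#' @param path internal, for error messages
#' @keywords internal
merge_config <- function(base, override, path = "") {
  if (is.null(override)) return(base)
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      cmhs_stop(sprintf("unknown config key '%s'", full), "cmhs_config_error")
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}
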