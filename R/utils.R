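## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so library calls that consume
#' randomness do not perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a component sub-seed from a master seed
#'
#' A master seed fans out to named sub-seeds (climate, routes, occupancy,
#' detection, background, partitions, model, threshold, ...) so pipeline
#' components can be varied independently while the whole run stays
#' reproducible. An optional index separates repeated draws (years,
#' replicates, species).
#'
#' @param master Integer master seed.
#' @param component Character label of the component.
#' @param index Optional non-negative integer (replicate/year/species index).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' fanout_seed(42, "climate")
#' fanout_seed(42, "partitions", index = 7)
fanout_seed <- function(master, component, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(component))
  ## deterministic string hash (FNV-1a 32-bit folded into the seed)
  h <- fnv1a32(paste0(component, ":", as.integer(index)))
  as.integer((abs(as.numeric(master)) * 2654435761 + h) %% 2147483647)
}

## 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  h
}

## Stable content hash used for run manifests: FNV-1a over the deparsed object.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- fnv1a32(s)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

## Stratified index sample: draws `fraction` of each level of `labels`
## (at least one per level), without replacement. Returns row indices.
stratified_sample <- function(labels, fraction) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    k <- max(1L, round(length(i) * fraction))
    if (k >= length(i)) i else sample(i, k)
  }), use.names = FALSE)
  sort(idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
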