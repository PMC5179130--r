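# Internal helpers shared across modules.

# Ordered taxonomic ranks, shallowest first.
TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

# Marker for an unassigned rank inside a lineage.
UNCLASSIFIED <- ""

is_unclassified <- function(x) is.na(x) | x == UNCLASSIFIED

rank_index <- function(level) {
  i <- match(level, TAXON_RANKS)
  if (is.na(i)) {
    stop("unknown taxonomic level '", level, "'; must be one of: ",
         paste(TAXON_RANKS, collapse = ", "), call. = FALSE)
  }
  i
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Small stable content hash (djb2 over the serialized object, 31 bit),
# used to stamp pipeline outputs with a config fingerprint.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop("'", name, "' must be a single finite number",
         if (is.finite(lower)) paste0(" >= ", lower), call. = FALSE)
  }
  invisible(x)
}
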