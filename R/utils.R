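# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (non-reproducible draw).
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a deterministic stage sub-seed from a base seed, kept within
# 32-bit integer range.
derive_seed <- function(seed, stage) {
    if (is.null(seed)) return(NULL)
    offsets <- c(genome = 101L, variants = 211L, truth = 307L, counts = 401L,
                 neighbor = 503L, overlap = 601L)
    stopifnot(stage %in% names(offsets))
    as.integer((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

assert_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) ||
        any(x < min) || any(x != floor(x)))
        stop(sprintf("'%s' must be integer-valued and >= %d", name, min),
             call. = FALSE)
    invisible(as.integer(x))
}

assert_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
    invisible(as.numeric(x))
}

empty_variant_df <- function() {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene_id = character(),
               stringsAsFactors = FALSE)
}
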