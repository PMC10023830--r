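# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All randomness in the package funnels through
# this, so one root seed makes every stage reproducible independently.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Derive a substream seed from a root seed and an offset < 100003, keeping
# the result inside the 32-bit integer range set.seed() accepts.
subSeed <- function(seed, offset) {
    as.integer((abs(seed) %% 20000) * 100003 + (offset %% 100003))
}

# Positive integer scalar check.
assertCount <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != floor(x))
        stop("'", what, "' must be a single positive integer", call. = FALSE)
    invisible(as.integer(x))
}

emptyTargets <- function() {
    data.frame(target_id = character(), organism = character(),
               known_action = character(), stringsAsFactors = FALSE)
}
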