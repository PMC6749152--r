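# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Derive an independent per-component stream from the global seed, so adding
# one generator never shifts another's output. Kept below 2^31 - 1.
componentSeed <- function(seed, component) {
    offsets <- c(expression = 11L, mir_expression = 23L, interactions = 37L,
                 known_lists = 53L, genesets = 71L, powerlaw = 89L)
    if (!component %in% names(offsets))
        stop("unknown RNG component: ", component)
    as.integer((as.numeric(seed) * 7919 + offsets[[component]]) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
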