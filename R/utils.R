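# internal helpers shared across modules

# Evaluate `expr` with the global RNG seeded to `seed`, restoring any
# pre-existing RNG state afterwards so generator calls do not perturb the
# caller's stream.
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# percent formatting that echoes the paper-style rounding: one decimal by
# default, whole percents on request
pctValue <- function(count, total, digits = 1L) {
    round(100 * count / total, digits)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
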