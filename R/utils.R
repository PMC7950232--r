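# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards (same contract as stats::simulate).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Coerce a two-level grouping vector to a factor with the case level first
# when levels are recognisable, otherwise keep the supplied/alphabetical
# order. `case_level`, if given, wins.
as_group_factor <- function(labels, case_level = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2L)
    stop("labels must have exactly two levels, got: ",
         paste(levels(f), collapse = ", "))
  if (!is.null(case_level)) {
    if (!case_level %in% levels(f))
      stop("case_level '", case_level, "' not among label levels")
    f <- stats::relevel(f, ref = setdiff(levels(f), case_level))
  } else if (all(sort(levels(f)) == c("case", "control"))) {
    f <- factor(f, levels = c("control", "case"))
  }
  f
}

# levels(f)[2] is treated as the case (diseased) group throughout.
case_level_of <- function(f) levels(f)[2L]

stop_if_not_matrix <- function(x, what = "expression") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes in rows, samples in columns)")
  if (is.null(rownames(x)))
    stop(what, " matrix must have gene identifiers as rownames")
  invisible(x)
}
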