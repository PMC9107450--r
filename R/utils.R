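#' @importFrom methods new validObject is show
#' @importFrom stats rnorm runif rbinom sd var quantile lm coef vcov pnorm
#'   qnorm t.test wilcox.test kruskal.test aov anova plogis qlogis p.adjust
#'   approx optim complete.cases setNames aggregate as.formula droplevels
#'   quantile
#' @importFrom utils read.csv write.csv head tail
#' @importClassesFrom S4Vectors DataFrame
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream; seed = NULL leaves the stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertFiniteScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
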