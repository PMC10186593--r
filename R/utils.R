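#' @importFrom stats quantile rnorm rlnorm rnbinom runif sd var median
#' @importFrom utils write.table read.delim head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed: offset by the sum
# of the stage name's character codes, kept inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage))
  as.integer((as.integer(seed) + offset) %% .Machine$integer.max)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()] returning a named list of
#' character vectors (set name -> gene ids).
#'
#' @param path Path to a tab-delimited GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled; defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  desc <- if (is.null(description)) names(sets) else
    rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Consistent TSV writers/readers for package artifacts.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
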