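#' @importFrom stats median pnorm pt p.adjust phyper sd var quantile rnbinom
#'   runif rbinom rpois t.test wilcox.test fisher.test cor setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# Derive a reproducible sub-stream seed from a master seed and an offset.
# Keeps results for one output independent of how many draws another output
# consumed. Kept below 2^31 - 1.
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 10007) %% 2147483629
}

with_seed <- function(seed, code) {
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
  force(code)
}

# Half-open [a, b) interval overlap width; intervals are 0-based half-open
# throughout the package (BED convention).
overlap_width <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
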