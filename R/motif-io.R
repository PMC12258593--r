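#' Read motifs in MEME minimal format
#'
#' Parses MOTIF blocks with their letter-probability matrices and the
#' optional background letter frequencies line.
#'
#' @param path MEME minimal text file.
#' @param pseudocount regularization passed to \code{pwm}.
#' @return named list of \code{pwm} objects.
#' @export
read_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    f <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (mi in motif_i) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[mi:length(lines)])[1] + mi - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4)))
    out[[id]] <- pwm(t(mat), id = id, background = bg,
                     pseudocount = pseudocount, is_counts = FALSE)
  }
  out
}

#' Read JASPAR-style count matrices
#'
#' Parses records of the form \code{>ID name} followed by four lines
#' \code{A [ 1 2 3 ]} etc.
#'
#' @param path JASPAR pfm text file.
#' @param pseudocount JASPAR-style pseudocount (default 0.8).
#' @return named list of \code{pwm} objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  out <- list()
  for (h in hdr) {
    id <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]][1]
    mat <- do.call(rbind, lapply(lines[h + 1:4], function(r) {
      as.numeric(regmatches(r, gregexpr("[0-9.]+", r))[[1]])
    }))
    out[[id]] <- pwm(mat, id = id, pseudocount = pseudocount,
                     is_counts = TRUE)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of \code{pwm} objects.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25",
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", m$width),
               con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$probs[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
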