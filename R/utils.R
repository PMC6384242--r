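# Shared low-level helpers: tolerant TSV reading for the CTD-style flat
# files (comment-prefixed headers, CRLF endings, trailing empty columns).

read_flat_tsv <- function(path, n_cols, col_names, comment_char = "#",
                          what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("input error: %s not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, comment_char) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character()), n_cols), col_names))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lengths(parts)
  # trailing empty columns are tolerated: pad short rows missing at most
  # the final columns only when the line ends without them
  bad <- fields > n_cols | fields < n_cols - 2L
  if (any(bad)) {
    stop(sprintf(
      "parse error: line %d of %s has %d columns, expected %d",
      line_no[which(bad)[1]], path, fields[which(bad)[1]], n_cols
    ), call. = FALSE)
  }
  parts <- lapply(parts, function(p) c(p, rep("", n_cols - length(p))))
  mat <- matrix(unlist(parts, use.names = FALSE),
    ncol = n_cols, byrow = TRUE
  )
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- col_names
  out
}

# Count distinct pipe-separated tokens (e.g. PubMed IDs) in a field.
count_pipe_tokens <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), function(t) {
    t <- trimws(t)
    length(unique(t[nzchar(t)]))
  }, integer(1))
}

split_pipe <- function(x) {
  t <- trimws(unlist(strsplit(x, "|", fixed = TRUE), use.names = FALSE))
  t[nzchar(t)]
}

# Deterministic JSON writer: fixed key order as constructed, no scientific
# notation drift, trailing newline.
write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(txt, path)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, eol = "\n"
  )
  invisible(path)
}
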