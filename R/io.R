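# Readers for the package's external file formats.

#' Read RNA sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences (T converted to U).
#' @export
read_rna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(x)))
  stats::setNames(out, names(x))
}

#' Read a SHAPE reactivity profile
#'
#' Two-column TSV (position, reactivity), with or without a header.
#' Positions must be 1..L; missing positions become NA.
#'
#' @param path TSV file.
#' @param L expected sequence length (default: max position).
#' @return numeric vector of reactivities.
#' @export
read_shape_tsv <- function(path, L = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#")
  if (is.character(df[[1]])) df <- df[-1, , drop = FALSE]  # header row
  pos <- as.integer(df[[1]]); val <- as.numeric(df[[2]])
  if (is.null(L)) L <- max(pos)
  out <- rep(NA_real_, L)
  out[pos] <- val
  out
}

#' Read a YAML run configuration
#'
#' Recognized top-level sections `vqvae`, `generator`, `score`, `search`
#' are merged over the corresponding config defaults.
#'
#' @param path YAML file.
#' @return list with `vqvae`, `generator`, `score`, `search` configs.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, over) {
    over <- over[intersect(names(over), names(formals(ctor)))]
    do.call(ctor, over)
  }
  list(vqvae = build(codec_config, y$vqvae %||% list()),
       generator = build(gen_config, y$generator %||% list()),
       score = build(score_config, y$score %||% list()),
       search = build(search_config, y$search %||% list()))
}
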