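#' Read a counts TSV and a lengths TSV into a count matrix
#'
#' The counts file is tab-separated with a header row and the transcript id
#' in column 1; the lengths file has columns transcript id and length_bp.
#'
#' @param counts_path,lengths_path file paths.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, lengths_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(len[[2]], len[[1]]))
}

#' Write a count matrix as counts and lengths TSVs
#'
#' @param cm a [count_matrix()].
#' @param counts_path,lengths_path output paths.
#' @export
write_counts <- function(cm, counts_path, lengths_path) {
  out <- data.frame(transcript = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  len <- data.frame(transcript = names(cm$lengths), length_bp = cm$lengths)
  utils::write.table(len, lengths_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read sample metadata (sample, taxon, zone) from TSV
#' @param path file path.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "taxon", "zone")
  if (!all(need %in% names(md)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  md
}

#' Read a soil table (site, group, 14 variables) from CSV
#' @param path file path.
#' @export
read_soil <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(soil_variables, colnames(tab))
  if (length(miss) > 0)
    stop("soil CSV lacks variables: ", paste(miss, collapse = ", "))
  tab
}

#' Read a GO DAG from a 2-column child-parent edge TSV
#' @param path file path.
#' @return a [go_dag()].
#' @export
read_go_edges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(e)[1:2] <- c("child", "parent")
  go_dag(e)
}

#' Read a GO DAG from a minimal OBO subset (id, name, is_a stanza lines)
#' @param path file path to an OBO-format file.
#' @return a [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0); term_names <- character(0)
  edges <- list()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- sub("^id:\\s*", "", ln)
      terms <- c(terms, cur)
    } else if (grepl("^name:", ln) && !is.na(cur)) {
      term_names[cur] <- sub("^name:\\s*", "", ln)
    } else if (grepl("^is_a:", ln) && !is.na(cur)) {
      parent <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", ln))
      edges[[length(edges) + 1]] <- data.frame(child = cur, parent = parent,
                                               stringsAsFactors = FALSE)
    }
  }
  go_dag(if (length(edges) > 0) do.call(rbind, edges) else NULL,
         terms = terms, term_names = term_names)
}

#' Read a gene-to-term annotation TSV
#' @param path file path (columns gene, term).
#' @export
read_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(a)[1:2] <- c("gene", "term")
  a
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
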