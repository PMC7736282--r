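# Gapped Karlin-Altschul parameters for BLOSUM62 with affine gap costs
# (open 11, extend 1), as used by protein BLAST.
KA_LAMBDA <- 0.267
KA_K <- 0.041

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

check_aa <- function(sequence, id = "sequence") {
  chars <- unique(strsplit(toupper(sequence), "")[[1]])
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad)) {
    stop(id, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read a multiple sequence alignment
#'
#' @param path Alignment path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return Named character vector of equal-length aligned rows.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  out <- as.character(aln)
  names(out) <- sub("\\s.*$", "", rownames(aln))
  out
}

#' Local pairwise similarity of two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1), with the E-value from the standard extreme-value
#' statistic `E = K * m * n * exp(-lambda * S)` using the gapped BLOSUM62
#' parameters -- a desk-scale re-creation of what an all-versus-all protein
#' BLAST reports. Percent identity is computed over aligned columns.
#'
#' @param a,b Sequences (character strings) or named length-1 character
#'   vectors (names become ids).
#' @param db_size Effective database size in residues (defaults to the
#'   length of `b`, i.e. a two-sequence comparison).
#' @return One-row data frame: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `bit_score`.
#' @export
pairwise_similarity <- function(a, b, db_size = NULL) {
  ida <- if (!is.null(names(a))) names(a) else "query"
  idb <- if (!is.null(names(b))) names(b) else "subject"
  a <- toupper(unname(a)); b <- toupper(unname(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  check_aa(a, ida); check_aa(b, idb)
  if (is.null(db_size)) db_size <- nchar(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(aln)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(pat)
  ident <- sum(strsplit(pat, "")[[1]] == strsplit(sub, "")[[1]])
  e <- KA_K * nchar(a) * db_size * exp(-KA_LAMBDA * s)
  data.frame(query_id = ida, subject_id = idb,
             percent_identity = 100 * ident / len,
             alignment_length = len, e_value = e,
             bit_score = (KA_LAMBDA * s - log(KA_K)) / log(2),
             stringsAsFactors = FALSE)
}

#' All-versus-all pairwise hits for a sequence set
#'
#' Runs [pairwise_similarity()] over every unordered pair, using the total
#' residue count of the set as the effective database size.
#'
#' @param sequences Named character vector of sequences.
#' @return Data frame of pairwise hits (one row per unordered pair).
#' @export
all_vs_all_hits <- function(sequences) {
  ids <- names(sequences)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  db <- sum(nchar(sequences))
  pairs <- utils::combn(seq_along(ids), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    pairwise_similarity(sequences[i], sequences[j], db_size = db)
  }))
}

#' Parse BLAST 12-column tabular output
#'
#' Reads the standard `-outfmt 6` format, keeping `query_id`, `subject_id`,
#' `percent_identity`, `alignment_length`, `e_value` and `bit_score`.
#' Reciprocal hits (A-B and B-A) are deduplicated keeping the lower E-value.
#'
#' @param path Tabular hits path.
#' @return Data frame of deduplicated hits.
#' @export
parse_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), e_value = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- vapply(fields, length, integer(1))
  if (any(nfield != 12L)) {
    stop("line ", which(nfield != 12L)[1],
         ": expected 12 tab-separated columns, found ",
         nfield[nfield != 12L][1])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     percent_identity = as.numeric(m[, 3]),
                     alignment_length = as.integer(m[, 4]),
                     e_value = as.numeric(m[, 11]),
                     bit_score = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  dedup_hits(hits)
}

#' Deduplicate reciprocal pairwise hits
#'
#' Keeps one row per unordered pair, the one with the lowest E-value.
#'
#' @param hits Data frame with `query_id`, `subject_id`, `e_value`.
#' @return Deduplicated data frame.
#' @export
dedup_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- ifelse(hits$query_id < hits$subject_id,
                paste(hits$query_id, hits$subject_id, sep = "\r"),
                paste(hits$subject_id, hits$query_id, sep = "\r"))
  ord <- order(key, hits$e_value)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a sequence-similarity network
#'
#' Nodes are sequence ids; an undirected edge joins two sequences exactly
#' when their best pairwise hit scores an E-value strictly below the
#' threshold. Self-hits never become edges; isolated nodes are retained and
#' connected components are labelled.
#'
#' @param hits Data frame of pairwise hits (deduplicated; [dedup_hits()] is
#'   applied defensively).
#' @param threshold E-value threshold (edge iff `e_value < threshold`).
#' @param nodes Optional extra node ids to include as isolated vertices.
#' @return An `igraph` graph with edge attributes `e_value`,
#'   `percent_identity`, vertex attribute `component` and graph attribute
#'   `threshold`.
#' @export
build_ssn <- function(hits, threshold = 1e-30, nodes = NULL) {
  hits <- dedup_hits(hits)
  ids <- sort(unique(c(hits$query_id, hits$subject_id, nodes)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  keep <- hits$e_value < threshold & hits$query_id != hits$subject_id
  edges <- hits[keep, , drop = FALSE]
  if (nrow(edges)) {
    g <- igraph::add_edges(g, as.vector(rbind(edges$query_id,
                                              edges$subject_id)))
    igraph::E(g)$e_value <- edges$e_value
    igraph::E(g)$percent_identity <- edges$percent_identity
  }
  igraph::V(g)$component <- igraph::components(g)$membership
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Extract an induced subnetwork
#'
#' @param network An SSN from [build_ssn()].
#' @param nodes Node ids to keep, or a single id with `component = TRUE` to
#'   take its whole connected component.
#' @param component Take the connected component of a seed node.
#' @return The induced subgraph, with graph attribute `median_identity`
#'   (median `percent_identity` over its edges).
#' @export
extract_subnetwork <- function(network, nodes, component = FALSE) {
  known <- igraph::V(network)$name
  missing <- setdiff(nodes, known)
  if (length(missing)) {
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  }
  if (component) {
    comp <- igraph::components(network)$membership
    nodes <- known[comp %in% comp[match(nodes, known)]]
  }
  sub <- igraph::induced_subgraph(network, nodes)
  med <- if (igraph::ecount(sub) > 0) {
    stats::median(igraph::E(sub)$percent_identity)
  } else {
    NA_real_
  }
  igraph::set_graph_attr(sub, "median_identity", med)
}

#' Map a reference residue position to an MSA column
#'
#' Returns the alignment column whose ungapped index in the reference row
#' equals `position` (1-based). Gap characters are `-` and `.`.
#'
#' @param msa Named character vector of aligned rows.
#' @param reference_id Name of the reference row.
#' @param position 1-based ungapped residue position in the reference.
#' @return Integer column index.
#' @export
map_reference_position <- function(msa, reference_id, position) {
  if (!reference_id %in% names(msa)) {
    stop("reference sequence '", reference_id, "' not in alignment")
  }
  row <- strsplit(msa[[reference_id]], "")[[1]]
  non_gap <- !(row %in% c("-", "."))
  if (position < 1 || position > sum(non_gap)) {
    stop("position ", position, " beyond the reference's ungapped length (",
         sum(non_gap), ")")
  }
  which(non_gap & cumsum(non_gap) == position)
}

#' Annotate network nodes by the residue at reference positions
#'
#' For each requested reference position, maps it to its MSA column and
#' reports the residue letter every node carries there -- e.g. which family
#' members hold an aspartate at the column aligned with the catalytic
#' lysine's neighbour K41. Nodes absent from the alignment are annotated
#' `NA` with a warning.
#'
#' @param network An SSN from [build_ssn()].
#' @param msa Named character vector of aligned rows.
#' @param reference_id Reference row name.
#' @param positions Integer vector of reference positions.
#' @return Named list (one element per position) of class
#'   `varsite_annotation`: each has `position`, `column`, `residues` (data
#'   frame `node`, `residue`) and `counts` (table of residue letters).
#' @export
annotate_nodes <- function(network, msa, reference_id, positions) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(nodes, names(msa))
  if (length(missing)) {
    warning("node(s) not in alignment, annotated NA: ",
            paste(missing, collapse = ", "))
  }
  out <- lapply(positions, function(p) {
    col <- map_reference_position(msa, reference_id, p)
    letters <- vapply(nodes, function(nd) {
      if (!nd %in% names(msa)) return(NA_character_)
      substr(msa[[nd]], col, col)
    }, character(1))
    res <- data.frame(node = nodes, residue = unname(letters),
                      stringsAsFactors = FALSE)
    ann <- list(position = p, column = col, residues = res,
                counts = table(res$residue, useNA = "no"))
    class(ann) <- "varsite_annotation"
    ann
  })
  names(out) <- as.character(positions)
  out
}

#' Per-column residue probabilities of an alignment
#'
#' Frequencies of each residue among non-gap rows per column -- the numbers
#' behind a sequence logo. The gap fraction is reported separately; an
#' all-gap column gets `NA` probabilities and is flagged.
#'
#' @param msa Named character vector of aligned rows.
#' @param columns Integer column indices.
#' @return A list of class `varsite_ppm`: `probabilities` (list per column
#'   of named numeric vectors summing to 1), `gap_fraction` (numeric per
#'   column), `all_gap` (logical per column).
#' @export
column_probabilities <- function(msa, columns) {
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  if (any(columns < 1 | columns > ncol(mat))) {
    stop("column index out of range (alignment has ", ncol(mat), " columns)")
  }
  probs <- list(); gapf <- numeric(); allgap <- logical()
  for (ci in columns) {
    col <- mat[, ci]
    gap <- col %in% c("-", ".")
    gapf <- c(gapf, mean(gap))
    if (all(gap)) {
      probs[[as.character(ci)]] <- NA
      allgap <- c(allgap, TRUE)
    } else {
      tab <- table(col[!gap])
      p <- as.numeric(tab) / sum(tab)
      names(p) <- names(tab)
      probs[[as.character(ci)]] <- p
      allgap <- c(allgap, FALSE)
    }
  }
  names(gapf) <- names(probs)
  names(allgap) <- names(probs)
  out <- list(probabilities = probs, gap_fraction = gapf, all_gap = allgap)
  class(out) <- "varsite_ppm"
  out
}

#' Write a network to GraphML
#'
#' @param network An igraph network.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Write a network edge list to CSV
#'
#' @param network An igraph network.
#' @param path Output path.
#' @export
write_network_csv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}
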