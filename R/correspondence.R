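#' Residue correspondence between two homologous systems
#'
#' A gapped one-to-one residue mapping between two homologs, typically
#' derived from a structural alignment.  Mapped rows carry an index on both
#' sides; an insertion in either system appears as a row with `NA` on the
#' other side.  Indices must be strictly increasing on both sides (the
#' alignment is colinear).
#'
#' @param index_a,index_b integer residue indices (1-based), `NA` for a gap.
#'   A row may not be `NA` on both sides.
#' @param labels character vector of length 2 naming the two systems.
#' @return an object of class `"residue_correspondence"`, a data frame with
#'   columns `index_a`, `index_b` and a `labels` attribute.
#' @export
residue_correspondence <- function(index_a, index_b,
                                   labels = c("A", "B")) {
  if (length(index_a) != length(index_b))
    stop("index vectors must have equal length")
  if (any(is.na(index_a) & is.na(index_b)))
    stop("a correspondence row cannot be a gap on both sides")
  for (v in list(index_a, index_b)) {
    x <- v[!is.na(v)]
    if (anyDuplicated(x)) stop("mapping must be one-to-one")
    if (is.unsorted(x, strictly = TRUE)) stop("indices must be strictly increasing")
  }
  structure(data.frame(index_a = as.integer(index_a),
                       index_b = as.integer(index_b)),
            labels = labels,
            class = c("residue_correspondence", "data.frame"))
}

#' Read a residue correspondence table from TSV
#'
#' Two-column tab-separated file (`indexA`, `indexB`) with `-` marking gaps.
#'
#' @param path input file.
#' @param labels system labels; default taken from the header.
#' @return a [residue_correspondence()].
#' @export
read_correspondence <- function(path, labels = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("correspondence table needs two columns")
  if (is.null(labels)) labels <- names(tab)[1:2]
  to_int <- function(x) suppressWarnings(ifelse(x == "-", NA_integer_, as.integer(x)))
  residue_correspondence(to_int(tab[[1]]), to_int(tab[[2]]), labels = labels)
}

#' Write a residue correspondence table as TSV
#' @param corr a [residue_correspondence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correspondence <- function(corr, path) {
  lab <- attr(corr, "labels")
  out <- data.frame(a = ifelse(is.na(corr$index_a), "-", corr$index_a),
                    b = ifelse(is.na(corr$index_b), "-", corr$index_b))
  names(out) <- c(paste0("index", lab[1]), paste0("index", lab[2]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identity correspondence over n residues
#' @param n residue count.
#' @param labels system labels.
#' @return a [residue_correspondence()].
#' @export
identity_correspondence <- function(n, labels = c("A", "B")) {
  residue_correspondence(seq_len(n), seq_len(n), labels = labels)
}

#' Map a per-residue profile of one system onto its homolog's numbering
#'
#' Pairs each value of system A with the corresponding residue index of
#' system B.  Gapped positions are flagged (`mapped = FALSE`), never
#' silently dropped.
#'
#' @param values numeric per-residue series of system A (residues `1..n`).
#' @param corr a [residue_correspondence()] covering all A indices present.
#' @return data frame `index_a`, `value`, `index_b`, `mapped`.
#' @export
map_profile <- function(values, corr) {
  n <- length(values)
  lut <- corr$index_b[match(seq_len(n), corr$index_a)]
  covered <- seq_len(n) %in% corr$index_a
  if (!all(covered))
    stop("residue index ", which(!covered)[1], " not covered by the correspondence")
  data.frame(index_a = seq_len(n), value = values,
             index_b = lut, mapped = !is.na(lut))
}

#' Map a residue pair through a correspondence
#' @param pairs two-column matrix/data.frame of A-side residue pairs.
#' @param corr a [residue_correspondence()].
#' @return data frame with B-side indices (`NA` where gapped).
#' @keywords internal
map_pairs <- function(pairs, corr) {
  lut <- function(i) corr$index_b[match(i, corr$index_a)]
  data.frame(a_i = pairs[[1]], a_j = pairs[[2]],
             b_i = lut(pairs[[1]]), b_j = lut(pairs[[2]]))
}

#' Named residue-interval domain definition
#'
#' Stores named residue-index intervals (a domain may be split over several
#' intervals, as in discontinuous barrel domains).
#'
#' @param intervals named list; each element a 2-column matrix or a vector
#'   `c(start, end)` (or a list of such) of 1-based residue bounds.
#' @param n_residues sequence length used for bounds checking.
#' @return class `"domain_definition"`: named list of 2-column matrices.
#' @export
domain_definition <- function(intervals, n_residues) {
  out <- lapply(intervals, function(iv) {
    m <- if (is.list(iv)) do.call(rbind, iv) else matrix(iv, ncol = 2, byrow = TRUE)
    if (any(m[, 1] > m[, 2])) stop("interval start exceeds end")
    if (any(m < 1L) || any(m > n_residues)) stop("interval outside sequence bounds")
    m
  })
  structure(out, n_residues = n_residues, class = "domain_definition")
}

#' Residues belonging to a named domain
#' @param dom a [domain_definition()].
#' @param name domain name.
#' @return sorted integer residue indices.
#' @export
domain_residues <- function(dom, name) {
  m <- dom[[name]]
  if (is.null(m)) stop("unknown domain: ", name)
  sort(unique(unlist(apply(m, 1, function(r) seq(r[1], r[2]), simplify = FALSE))))
}
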