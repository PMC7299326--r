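#' Read a gene-set annotation table
#'
#' Two formats: `two_column_tsv` (columns gene id, term id, optional third
#' column with the term name) and `gmt` (one term per line:
#' id, description, then member genes, tab-separated). Duplicate
#' (gene, term) memberships are collapsed.
#'
#' @param path File path.
#' @param format `"two_column_tsv"` or `"gmt"`.
#' @return List of class `"pibs_annotation"` with `terms` (named list of
#'   gene-id vectors), `term_names` (named character) and `genes` (all
#'   annotated genes).
#' @export
read_annotation <- function(path, format = c("two_column_tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty annotation file: ", path)
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 3)
    if (length(bad)) stop("malformed GMT line ", bad[1], ": needs id, ",
                          "description and at least one gene")
    ids <- vapply(parts, `[[`, character(1), 1L)
    terms <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(terms) <- ids
    term_names <- stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 2)
    if (length(bad)) stop("malformed line ", bad[1],
                          ": expected gene<TAB>term")
    gene <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
    nm <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                 character(1))
    terms <- lapply(split(gene, term), unique)
    term_names <- vapply(split(nm, term),
                         function(v) if (all(is.na(v))) NA_character_ else
                           stats::na.omit(v)[1], character(1))
  }
  if (any(lengths(terms) == 0)) stop("empty term(s) in annotation")
  structure(list(terms = terms, term_names = term_names,
                 genes = unique(unlist(terms, use.names = FALSE))),
            class = "pibs_annotation")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation in a gene set with
#' the upper-tail hypergeometric test (the overlap observed or larger,
#' given the term size, set size and universe size). Terms overlapping the
#' set by fewer than `min_overlap` genes are omitted; terms with identical
#' gene memberships (within the universe) are merged.
#'
#' @param test_set Character vector of gene ids; must lie in `universe`.
#' @param annotation A `"pibs_annotation"` from [read_annotation()], or a
#'   named list of gene-id vectors.
#' @param universe Character vector: the background gene universe
#'   (typically all post-filter tested genes).
#' @param min_overlap Minimum set-term overlap to report (default 2).
#' @param alpha Significance flag threshold on the raw p (default 0.05,
#'   strict `<`).
#' @return Data frame sorted by p: `term_id`, `term_name`, `overlap`,
#'   `term_size`, `set_size`, `universe_size`, `p`, `log10_p`, `fdr`,
#'   `significant`, `genes` (comma-joined overlapping ids), `merged_with`.
#' @export
ora <- function(test_set, annotation, universe, min_overlap = 2,
                alpha = 0.05) {
  terms <- if (inherits(annotation, "pibs_annotation")) annotation$terms
           else annotation
  term_names <- if (inherits(annotation, "pibs_annotation"))
    annotation$term_names else stats::setNames(rep(NA_character_,
                                                   length(terms)), names(terms))
  test_set <- unique(test_set); universe <- unique(universe)
  out_univ <- setdiff(test_set, universe)
  if (length(out_univ))
    stop("test genes outside the universe: ",
         paste(utils::head(out_univ, 5), collapse = ", "))

  in_univ <- lapply(terms, intersect, universe)
  keep <- lengths(in_univ) > 0
  in_univ <- in_univ[keep]; term_names <- term_names[names(in_univ)]

  # merge terms with identical memberships (trivial deduplication pass)
  key <- vapply(in_univ, function(g) paste(sort(g), collapse = "|"),
                character(1))
  first <- !duplicated(key)
  merged_with <- vapply(names(in_univ), function(id) {
    twin <- names(in_univ)[key == key[id] & names(in_univ) != id]
    if (length(twin)) paste(twin, collapse = ",") else ""
  }, character(1))
  in_univ <- in_univ[first]; term_names <- term_names[first]
  merged_with <- merged_with[first]

  rows <- lapply(names(in_univ), function(id) {
    tg <- in_univ[[id]]
    ov <- intersect(tg, test_set)
    if (length(ov) < min_overlap) return(NULL)
    h <- overlap_hypergeometric(length(tg), length(test_set), length(ov),
                                length(universe))
    data.frame(term_id = id, term_name = term_names[[id]],
               overlap = length(ov), term_size = length(tg),
               set_size = length(test_set), universe_size = length(universe),
               p = h$p, log10_p = h$log10_p,
               genes = paste(sort(ov), collapse = ","),
               merged_with = merged_with[[id]], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(0), term_name = character(0),
                      overlap = integer(0), term_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      p = numeric(0), log10_p = numeric(0), fdr = numeric(0),
                      significant = logical(0), genes = character(0),
                      merged_with = character(0)))
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p)
  tab$significant <- tab$p < alpha
  tab <- tab[order(tab$p, tab$term_id), ]
  rownames(tab) <- NULL
  tab[, c("term_id", "term_name", "overlap", "term_size", "set_size",
          "universe_size", "p", "log10_p", "fdr", "significant", "genes",
          "merged_with")]
}
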