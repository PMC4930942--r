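# IUPAC motif scanning and hypergeometric enrichment over promoter windows.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_expand_letter <- function(ch) {
  out <- IUPAC_MAP[[ch]]
  if (is.null(out)) abort(paste0("invalid IUPAC letter: ", ch))
  out
}

check_iupac <- function(iupac) {
  iupac <- toupper(iupac)
  if (nchar(iupac) == 0) abort("empty motif")
  letters <- strsplit(iupac, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_MAP))
  if (length(bad) > 0) abort(paste0("invalid IUPAC letter: ", bad[1]))
  iupac
}

iupac_revcomp <- function(iupac) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
}

#' Scan one sequence for an IUPAC motif on both strands
#'
#' Reports every occurrence of the motif on the plus strand and every
#' occurrence of its reverse complement (a minus-strand site) in plus-strand
#' coordinates. Overlapping matches are all reported. Ambiguity codes in the
#' motif expand to their base sets; an `N` in the *sequence* matches nothing
#' except a motif-position `N` (sequence letters are literal). For a
#' palindromic motif (equal to its own reverse complement) the minus-strand
#' scan would duplicate every plus-strand site, so only plus-strand sites
#' are reported.
#'
#' @param sequence One DNA sequence (A/C/G/T/N, case-insensitive).
#' @param iupac Motif as an IUPAC string.
#' @return Tibble with 1-based closed coordinates: `start`, `end`, `strand`
#'   ("+"/"-"), sorted by start.
#' @export
scan_motif <- function(sequence, iupac) {
  if (length(sequence) != 1 || !nzchar(sequence)) abort("sequence must be one non-empty string")
  iupac <- check_iupac(iupac)
  subj <- Biostrings::DNAString(toupper(sequence))
  hits <- function(pat, strand) {
    v <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj, fixed = "subject")
    tibble(start = Biostrings::start(v), end = Biostrings::end(v), strand = strand)
  }
  out <- hits(iupac, "+")
  rc <- iupac_revcomp(iupac)
  if (rc != iupac) out <- bind_rows(out, hits(rc, "-"))
  arrange(out, .data$start, .data$strand)
}

#' Genes whose promoter contains at least one motif match
#'
#' @param promoters Tibble with columns `gene_id`, `sequence`.
#' @param iupac Motif as an IUPAC string.
#' @return Character vector of gene ids with >= 1 match on either strand.
#' @export
genes_with_motif <- function(promoters, iupac) {
  stopifnot(all(c("gene_id", "sequence") %in% names(promoters)))
  iupac <- check_iupac(iupac)
  subj <- Biostrings::DNAStringSet(toupper(promoters$sequence))
  hit <- Biostrings::vcountPattern(Biostrings::DNAString(iupac), subj,
                                   fixed = "subject") > 0
  rc <- iupac_revcomp(iupac)
  if (rc != iupac) {
    hit <- hit | Biostrings::vcountPattern(Biostrings::DNAString(rc), subj,
                                           fixed = "subject") > 0
  }
  promoters$gene_id[hit]
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` carry the feature.
#'
#' @param k Feature-carrying genes in the set.
#' @param n Set size.
#' @param K Feature-carrying genes in the background.
#' @param N Background size.
#' @return Upper-tail p-value.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  ok <- k >= 0 & k <= pmin(n, K) & n <= N & K <= N & k >= pmax(0, n + K - N)
  if (any(!ok)) abort("hypergeometric bounds violated (need 0 <= k <= min(n, K), n <= N, K <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Motif enrichment of a gene set against a background
#'
#' For each motif (and each requested composite), counts the genes in the set
#' and in the background whose promoter contains at least one match and
#' computes the hypergeometric upper-tail p-value. A composite counts a gene
#' when it contains *any* of its member motifs (`composite_mode = "any"`,
#' the default) or *all* of them (`"all"`).
#'
#' @param promoters Tibble with `gene_id`, `sequence`; must cover every gene.
#' @param motifs Tibble with `name`, `iupac` (default [default_motifs()]).
#' @param gene_set Character vector of gene ids, a subset of `background`.
#' @param background Character vector of gene ids (the array universe).
#' @param composites Named list of character vectors of motif names, e.g.
#'   `list(GBOX_PBE = c("GBOX", "PBE"))`.
#' @param composite_mode "any" (presence of either element) or "all"
#'   (co-occurrence).
#' @param alpha Significance threshold reported in the `significant` column.
#' @return Tibble: motif, k, n, K, N, fraction_in_set, p_value, significant.
#' @export
enrich_gene_set <- function(promoters, motifs = default_motifs(), gene_set,
                            background,
                            composites = list(GBOX_PBE = c("GBOX", "PBE")),
                            composite_mode = c("any", "all"),
                            alpha = 0.05) {
  composite_mode <- match.arg(composite_mode)
  if (!all(gene_set %in% background)) abort("gene_set must be a subset of background")
  missing <- setdiff(background, promoters$gene_id)
  if (length(missing) > 0) {
    abort(paste0("genes missing promoters: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..." else ""))
  }
  prom <- promoters[promoters$gene_id %in% background, ]
  present <- lapply(setNames(motifs$iupac, motifs$name), function(iu) {
    genes_with_motif(prom, iu)
  })
  if (length(composites) > 0) {
    for (nm in names(composites)) {
      members <- composites[[nm]]
      bad <- setdiff(members, motifs$name)
      if (length(bad) > 0) abort(paste0("composite references unknown motif: ", bad[1]))
      sets <- present[members]
      present[[nm]] <- if (composite_mode == "any") {
        Reduce(union, sets)
      } else {
        Reduce(intersect, sets)
      }
    }
  }
  N <- length(background)
  n <- length(gene_set)
  purrr::map_dfr(names(present), function(nm) {
    hit <- present[[nm]]
    K <- length(intersect(hit, background))
    k <- length(intersect(hit, gene_set))
    p <- hypergeom_enrichment(k, n, K, N)
    tibble(motif = nm, k = k, n = n, K = K, N = N,
           fraction_in_set = if (n > 0) k / n else NA_real_,
           p_value = p, significant = p <= alpha)
  })
}

#' Category enrichment of a gene set against a background
#'
#' Generic hypergeometric enrichment with category membership (e.g. a
#' user-supplied GO or localization annotation) in place of motif presence.
#'
#' @param annotation Tibble with columns `gene_id`, `category` (one row per
#'   gene-category pair).
#' @param gene_set,background Character vectors of gene ids,
#'   `gene_set` a subset of `background`.
#' @param alpha Significance threshold for the `significant` column.
#' @return Tibble: category, k, n, K, N, fraction_in_set, p_value, significant.
#' @export
category_enrichment <- function(annotation, gene_set, background, alpha = 0.05) {
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  if (!all(gene_set %in% background)) abort("gene_set must be a subset of background")
  ann <- annotation[annotation$gene_id %in% background, ]
  cats <- unique(annotation$category)
  N <- length(background)
  n <- length(gene_set)
  purrr::map_dfr(cats, function(cc) {
    hit <- unique(ann$gene_id[ann$category == cc])
    K <- length(hit)
    k <- length(intersect(hit, gene_set))
    p <- hypergeom_enrichment(k, n, K, N)
    tibble(category = cc, k = k, n = n, K = K, N = N,
           fraction_in_set = if (n > 0) k / n else NA_real_,
           p_value = p, significant = p <= alpha)
  })
}
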