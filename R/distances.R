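# Uncorrected p-distances for labelled COI/COII alignments and the
# within/between-OTU group-mean table.

#' Read a labelled FASTA alignment
#'
#' Reads an aligned FASTA file and attaches OTU labels (and optional
#' sublabels, e.g. the two haplogroups of one OTU) from a label map.
#'
#' @param path FASTA file of aligned sequences (equal lengths).
#' @param label_map Data.frame with columns `record_id`, `otu` and
#'   optionally `sublabel`; every record id in the FASTA must be present.
#' @param gene Gene name stored with the alignment (e.g. `"COI"`).
#' @return An object of class `labelled_alignment`: a list with the
#'   character matrix `seqs` (records in rows), `id`, `otu`, `sublabel`
#'   and `gene`.
#' @export
read_labelled_fasta <- function(path, label_map, gene = "COI") {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  chars <- lapply(as.character(seqs), toupper)
  labelled_alignment(chars, names(seqs), label_map, gene)
}

#' Construct a labelled alignment from sequences in memory
#'
#' @param seqs Named list of character vectors (one per record) or a
#'   character vector of strings.
#' @param ids Record identifiers (defaults to the names of `seqs`).
#' @param label_map As in [read_labelled_fasta()].
#' @param gene Gene name.
#' @return A `labelled_alignment`.
#' @export
labelled_alignment <- function(seqs, ids = names(seqs), label_map,
                               gene = "COI") {
  if (is.character(seqs)) seqs <- strsplit(toupper(seqs), "")
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  if (is.null(ids)) stop("record ids are required")
  missing <- setdiff(ids, label_map$record_id)
  if (length(missing))
    stop("labelling error: no OTU label for record(s) ",
         paste(missing, collapse = ", "))
  i <- match(ids, label_map$record_id)
  m <- do.call(rbind, lapply(seqs, toupper))
  rownames(m) <- ids
  structure(list(seqs = m, id = ids,
                 otu = as.character(label_map$otu[i]),
                 sublabel = if ("sublabel" %in% names(label_map))
                   as.character(label_map$sublabel[i]) else
                     rep(NA_character_, length(ids)),
                 gene = gene, length = unname(lens[1])),
            class = "labelled_alignment")
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching columns among the comparable columns, where a
#' column is comparable iff both characters are unambiguous bases
#' (A, C, G or T): gaps, N and IUPAC ambiguity codes are deleted pairwise.
#'
#' @param seq_a,seq_b Character vectors or single strings of equal length.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when no column
#'   is comparable.
#' @export
p_distance <- function(seq_a, seq_b) {
  if (is.character(seq_a) && length(seq_a) == 1L)
    seq_a <- strsplit(seq_a, "")[[1L]]
  if (is.character(seq_b) && length(seq_b) == 1L)
    seq_b <- strsplit(seq_b, "")[[1L]]
  if (length(seq_a) != length(seq_b)) stop("sequences of unequal length")
  a <- toupper(seq_a); b <- toupper(seq_b)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    warning("no comparable columns; distance undefined")
    return(NA_real_)
  }
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Group-mean p-distance table for one gene
#'
#' Computes all pairwise uncorrected p-distances and averages them within
#' and between OTUs: `between(A, B)` is the mean over all cross pairs and
#' `within(A)` the mean over all unordered intra-OTU pairs (`NA` for
#' single-sequence OTUs). Undefined pairwise distances are excluded and
#' counted.
#'
#' @param alignment A `labelled_alignment`.
#' @param deletion `"pairwise"` (default) deletes non-ACGT columns per
#'   pair; `"complete"` removes every column containing any non-ACGT
#'   character before computing distances.
#' @param group `"otu"` or `"sublabel"` (sublabels fall back to the OTU
#'   label where absent).
#' @return An object of class `group_distance_table` with `within` (named
#'   vector of fractions), `between` (symmetric matrix), pair counts, the
#'   number of excluded pairs and the gene name.
#' @export
group_mean_distances <- function(alignment, deletion = c("pairwise",
                                                         "complete"),
                                 group = c("otu", "sublabel")) {
  stopifnot(inherits(alignment, "labelled_alignment"))
  deletion <- match.arg(deletion)
  group <- match.arg(group)
  g <- if (group == "sublabel") {
    ifelse(is.na(alignment$sublabel), alignment$otu, alignment$sublabel)
  } else alignment$otu
  m <- alignment$seqs
  if (deletion == "complete") {
    keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- suppressWarnings(p_distance(m[i, ], m[j, ]))
    }
  }
  gl <- sort(unique(g))
  within <- stats::setNames(rep(NA_real_, length(gl)), gl)
  n_within <- stats::setNames(rep(0L, length(gl)), gl)
  between <- matrix(NA_real_, length(gl), length(gl),
                    dimnames = list(gl, gl))
  n_between <- between
  excluded <- 0L
  for (ai in seq_along(gl)) {
    ia <- which(g == gl[ai])
    if (length(ia) >= 2L) {
      vals <- d[ia, ia][upper.tri(d[ia, ia])]
      excluded <- excluded + sum(is.na(vals))
      within[ai] <- mean(vals, na.rm = TRUE)
      n_within[ai] <- sum(!is.na(vals))
    }
    for (bi in seq_along(gl)) {
      if (bi <= ai) next
      ib <- which(g == gl[bi])
      vals <- d[ia, ib]
      excluded <- excluded + sum(is.na(vals))
      if (all(is.na(vals))) {
        warning("all pairwise distances undefined for ", gl[ai], " vs ",
                gl[bi])
      }
      between[ai, bi] <- between[bi, ai] <- mean(vals, na.rm = TRUE)
      n_between[ai, bi] <- n_between[bi, ai] <- sum(!is.na(vals))
    }
  }
  structure(list(within = within, between = between,
                 n_within = n_within, n_between = n_between,
                 excluded = excluded, gene = alignment$gene,
                 deletion = deletion),
            class = "group_distance_table")
}

#' @export
print.group_distance_table <- function(x, ...) {
  cat("<group_distance_table>", x$gene, "(", x$deletion, "deletion )\n")
  m <- round(100 * x$between, 1)
  diag(m) <- round(100 * x$within, 1)
  print(m)
  invisible(x)
}

#' Mirror two gene tables into one matrix
#'
#' Lays out the group means the way the published distance table does: the
#' first gene above the diagonal, the second below, and the first gene's
#' within-group means on the diagonal, as rounded percentages.
#'
#' @param tbl_upper,tbl_lower `group_distance_table`s on the same OTU set
#'   (e.g. COI and COII).
#' @param digits Decimal places of the percentages.
#' @return A numeric matrix of percentages.
#' @export
mirror_distance_tables <- function(tbl_upper, tbl_lower, digits = 1) {
  gl <- rownames(tbl_upper$between)
  stopifnot(identical(gl, rownames(tbl_lower$between)))
  m <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  m[upper.tri(m)] <- tbl_upper$between[upper.tri(m)]
  m[lower.tri(m)] <- tbl_lower$between[lower.tri(m)]
  diag(m) <- tbl_upper$within
  round(100 * m, digits)
}

#' Simulate an OTU-structured alignment
#'
#' Generates one ancestral sequence per main clade, then per-OTU and
#' per-record substitutions, producing an alignment whose between-clade
#' mean distances are controlled by the mutation counts. Useful as a
#' synthetic stand-in for testing the distance machinery.
#'
#' @param otus Named list: OTU name -> number of records.
#' @param clades Named character: OTU name -> clade name.
#' @param length Alignment length in columns.
#' @param clade_subs Substitutions separating each clade from the root.
#' @param otu_subs Substitutions separating each OTU from its clade.
#' @param record_subs Substitutions per individual record.
#' @param gap_prob Per-site gap probability in each record.
#' @param gene Gene name.
#' @param seed Integer seed.
#' @return A `labelled_alignment` (synthetic).
#' @export
simulate_alignment <- function(otus, clades, length = 800,
                               clade_subs = 20, otu_subs = 4,
                               record_subs = 1, gap_prob = 0,
                               gene = "COI", seed = 1L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    mutate <- function(s, k) {
      pos <- sample(length, k)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      s
    }
    clade_seq <- lapply(unique(clades), function(cl) mutate(root, clade_subs))
    names(clade_seq) <- unique(clades)
    seqs <- list(); ids <- character(0); otu_lab <- character(0)
    for (o in names(otus)) {
      os <- mutate(clade_seq[[clades[[o]]]], otu_subs)
      for (i in seq_len(otus[[o]])) {
        s <- mutate(os, record_subs)
        if (gap_prob > 0) s[stats::runif(length) < gap_prob] <- "-"
        ids <- c(ids, sprintf("%s_%02d", o, i))
        otu_lab <- c(otu_lab, o)
        seqs[[length(seqs) + 1L]] <- s
      }
    }
    labelled_alignment(seqs, ids,
                       data.frame(record_id = ids, otu = otu_lab,
                                  stringsAsFactors = FALSE), gene)
  })
}
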