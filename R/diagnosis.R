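# Rule-based diagnostic trait matrix for the four named lineages, and
# flagging of putative hybrids from intermediate song characters.

# One row per taxonomically relevant trait. Expectation symbols per taxon:
# "+"/"++" the trait is expected TRUE, "-"/"--" expected FALSE; double
# symbols mark characters that were flawless in the reference data set
# (weight 2 in the pass score); "?" and "+/-" rows are not evaluable for
# that taxon.
trait_matrix_rows <- function(alt_threshold = 750) {
  list(
    list(id = "coi_near_cerdaniensis",
         desc = "COI distance to C. cerdaniensis < 1.5%",
         value = function(r) if (is.na(r$coi_dist_to_cerdaniensis)) NA
           else r$coi_dist_to_cerdaniensis < 0.015,
         petr = "++", brev = "--", hipp = "--", lito = "--"),
    list(id = "ph2_rate_low",
         desc = "phrase-2 rate < 0.03 at population level",
         value = function(r) if (is.na(r$ph2_population_rate)) NA
           else r$ph2_population_rate < 0.03,
         petr = "++", brev = "++", hipp = "--", lito = "--"),
    list(id = "ep_l_1_high",
         desc = "EP_L/1 > 20% of the total power increase",
         value = function(r) if (is.na(r$ep_l_1)) NA else r$ep_l_1 > 0.20,
         petr = "+", brev = "-", hipp = "-", lito = "?"),
    list(id = "ied_s_l_min_short",
         desc = "IED_S_L minimum < 0.34 s",
         value = function(r) if (is.na(r$ied_s_l_min)) NA
           else r$ied_s_l_min < 0.34,
         petr = "++", brev = "--", hipp = "--", lito = "++"),
    list(id = "e_in_number_low",
         desc = "E_IN number < 2.5",
         value = function(r) if (is.na(r$e_in_number)) NA
           else r$e_in_number < 2.5,
         petr = "+", brev = "-", hipp = "--", lito = "--"),
    list(id = "junction_light",
         desc = "basal junction of anal veins light",
         value = function(r) r$junction_light,
         petr = "+", brev = "--", hipp = "-", lito = "++"),
    list(id = "apical8_dark",
         desc = "veins of apical cell 8 predominantly dark",
         value = function(r) r$apical8_dark_rims,
         petr = "+", brev = "+", hipp = "++", lito = "-"),
    list(id = "postclypeus_plain",
         desc = "postclypeus without yellowish spot",
         value = function(r) if (is.na(r$postclypeus_spot)) NA
           else !r$postclypeus_spot,
         petr = "+", brev = "+", hipp = "+", lito = "-"),
    list(id = "high_altitude",
         desc = sprintf("habitat above %g m asl", alt_threshold),
         value = function(r) if (is.na(r$altitude_m)) NA
           else r$altitude_m > alt_threshold,
         petr = "+/-", brev = "-", hipp = "+", lito = "--"),
    list(id = "not_salt_marsh",
         desc = "habitat not in salt marshes",
         value = function(r) if (is.na(r$salt_marsh)) NA else !r$salt_marsh,
         petr = "++", brev = "++", hipp = "++", lito = "--")
  )
}

.trait_fields <- c("ph2_population_rate", "ep_l_1", "ied_s_l_min",
                   "e_in_number", "junction_light", "apical8_dark_rims",
                   "postclypeus_spot", "altitude_m", "salt_marsh",
                   "coi_dist_to_cerdaniensis")

as_trait_record <- function(record) {
  r <- as.list(record)
  for (f in .trait_fields) if (is.null(r[[f]])) r[[f]] <- NA
  r
}

#' Evaluate the diagnostic trait matrix for one record
#'
#' Scores a record of acoustic, morphological, ecological and genetic
#' traits against the per-taxon expectations of the diagnostic matrix.
#' Each evaluable trait passes when the observed state matches the taxon's
#' expectation; flawless characters (double symbols) carry weight 2. The
#' best taxon maximizes the weighted pass proportion over its evaluable
#' rows; ties give `"ambiguous"`. Rows with `"?"`/`"+/-"` expectations or
#' missing values count as not evaluable.
#'
#' @param record A list or one-row data.frame; any of the fields
#'   `ph2_population_rate`, `ep_l_1`, `ied_s_l_min`, `e_in_number`,
#'   `junction_light`, `apical8_dark_rims`, `postclypeus_spot`,
#'   `altitude_m`, `salt_marsh`, `coi_dist_to_cerdaniensis` may be missing
#'   (`NA`), but at least two must be present.
#' @param alt_threshold Altitude cut in metres for the mountain-habitat row
#'   (the published band is 700-800 m).
#' @return An object of class `diagnosis_result` with a per-taxon table of
#'   passes/failures/not-evaluable counts and weighted scores, and
#'   `best_taxon`.
#' @export
evaluate_trait_matrix <- function(record, alt_threshold = 750) {
  r <- as_trait_record(record)
  rows <- trait_matrix_rows(alt_threshold)
  vals <- vapply(rows, function(row) {
    v <- row$value(r)
    if (is.null(v) || is.na(v)) NA else as.logical(v)
  }, logical(1))
  if (sum(!is.na(vals)) < 2L)
    stop("insufficient data: fewer than 2 evaluable traits")
  taxa <- c("petr", "brev", "hipp", "lito")
  per <- lapply(taxa, function(tx) {
    passes <- 0L; failures <- 0L; ne <- 0L; wpass <- 0; wtot <- 0
    for (i in seq_along(rows)) {
      sym <- rows[[i]][[tx]]
      if (sym %in% c("?", "+/-") || is.na(vals[i])) { ne <- ne + 1L; next }
      expected <- substr(sym, 1, 1) == "+"
      w <- if (nchar(sym) == 2L) 2 else 1
      wtot <- wtot + w
      if (vals[i] == expected) { passes <- passes + 1L; wpass <- wpass + w }
      else failures <- failures + 1L
    }
    data.frame(taxon = tx, passes = passes, failures = failures,
               not_evaluable = ne,
               score = if (wtot > 0) wpass / wtot else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  best <- tab$taxon[which.max(tab$score)]
  if (sum(abs(tab$score - max(tab$score, na.rm = TRUE)) < 1e-9,
          na.rm = TRUE) > 1L) best <- "ambiguous"
  structure(list(per_taxon = tab, best_taxon = best,
                 trait_values = stats::setNames(
                   vals, vapply(rows, `[[`, character(1), "id"))),
            class = "diagnosis_result")
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat("<diagnosis_result> best taxon:", x$best_taxon, "\n")
  print(x$per_taxon, row.names = FALSE)
  invisible(x)
}

#' Diagnose a table of trait records
#'
#' @param records Data.frame of trait records (one row per individual).
#' @param alt_threshold As in [evaluate_trait_matrix()].
#' @return Data.frame with `best_taxon` and per-taxon scores per record.
#' @export
diagnose_records <- function(records, alt_threshold = 750) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    d <- evaluate_trait_matrix(records[i, , drop = FALSE], alt_threshold)
    sc <- stats::setNames(d$per_taxon$score,
                          paste0("score_", d$per_taxon$taxon))
    cbind(data.frame(best_taxon = d$best_taxon, stringsAsFactors = FALSE),
          as.data.frame(as.list(sc)))
  })
  res <- do.call(rbind, out)
  if (!is.null(records$record_id)) res <- cbind(
    data.frame(record_id = records$record_id, stringsAsFactors = FALSE), res)
  if (!is.null(records$otu)) res$true_otu <- records$otu
  res
}

#' Flag putative hybrids from intermediate song characters
#'
#' An individual is flagged when, across the three diagnostic song
#' characters (standardized power EP_L/1, minimum inter-echeme duration and
#' introductory-chirp number, each scored by partial-residual
#' classification against the reference OTU pair), at least two characters
#' fall in the overlap of the two reference variances, or the characters
#' split between the two taxa.
#'
#' @param classifications Named list of `residual_classification` objects
#'   (one per song character), all over the same individuals in the same
#'   order.
#' @return Data.frame with the per-character zones, `hybrid_flag` and the
#'   contributing characters.
#' @export
flag_hybrids <- function(classifications) {
  stopifnot(length(classifications) >= 2L)
  labs <- lapply(classifications, function(cl) {
    l <- cl$label
    l[l == "fits_reference"] <- "reference"
    l[l == "fits_contrast"] <- "contrast"
    l
  })
  n <- length(labs[[1L]])
  stopifnot(all(lengths(labs) == n))
  zone <- do.call(cbind, labs)
  colnames(zone) <- names(classifications)
  flag <- logical(n); why <- character(n)
  for (i in seq_len(n)) {
    z <- zone[i, ]
    n_over <- sum(z == "overlap")
    split <- any(z == "reference") && any(z == "contrast")
    flag[i] <- n_over >= 2L || split
    why[i] <- if (!flag[i]) "" else if (split)
      "characters split between taxa" else
      paste(colnames(zone)[z == "overlap"], collapse = "+")
  }
  cbind(as.data.frame(zone, stringsAsFactors = FALSE),
        data.frame(hybrid_flag = flag, contributing = why,
                   stringsAsFactors = FALSE))
}
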