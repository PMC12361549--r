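## Peptide-level quality control.
##
## Reads Proteome Discoverer-style peptide quantification exports and
## applies the record-level filters used for label-free aging proteomics:
## a peptide survives iff it has a master protein accession, carries no
## disqualifying quantification flag (NoQuanValues / NoneMonoisotopic),
## maps to a single protein group, is an unambiguous PSM, and has both
## posterior error probability and q-value <= 0.05 (inclusive thresholds).

.REQUIRED_COLUMNS <- list(
  sequence         = c("Sequence", "Annotated.Sequence"),
  master_accession = c("Master.Protein.Accessions"),
  n_protein_groups = c("Number.of.Protein.Groups", "X..Protein.Groups"),
  psm_ambiguity    = c("PSM.Ambiguity"),
  quan_info        = c("Quan.Info"),
  pep              = c("PEP", "Percolator.PEP"),
  q_value          = c("q.Value", "qvalue", "Percolator.q.Value"))

#' Read a peptide-level quantification table
#'
#' Parses a TSV export (Proteome Discoverer dialect) into a standardized
#' record table: annotation columns are renamed to
#' `sequence, master_accession, n_protein_groups, psm_ambiguity, quan_info,
#' pep, q_value`, and one intensity column per metadata sample is resolved
#' (either named by the sample id directly or prefixed `Abundance.`).
#' Unparseable intensity cells become `NA` and are counted in the
#' `parse_failures` attribute; unrecognized extra columns are dropped with a
#' message.
#'
#' @param path TSV file path.
#' @param metadata data.frame with at least `sample_id`; columns are
#'   returned in metadata order.
#' @return data.frame of peptide records with attribute `parse_failures`.
#' @export
readPeptideTable <- function(path, metadata) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = TRUE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(.REQUIRED_COLUMNS)) {
    hit <- intersect(.REQUIRED_COLUMNS[[canon]], names(raw))
    if (length(hit) == 0L)
      stop("peptide table is missing required column for '", canon,
           "' (expected one of: ",
           paste(.REQUIRED_COLUMNS[[canon]], collapse = ", "), ")")
    out[[canon]] <- raw[[hit[1]]]
  }
  out$pep <- suppressWarnings(as.numeric(out$pep))
  out$q_value <- suppressWarnings(as.numeric(out$q_value))

  parseFailures <- 0L
  sampleCols <- character(nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    cand <- c(sid, make.names(sid), paste0("Abundance.", make.names(sid)))
    hit <- intersect(cand, names(raw))
    if (length(hit) == 0L)
      stop("no intensity column found for sample '", sid, "'")
    sampleCols[i] <- hit[1]
    v <- raw[[hit[1]]]
    nonEmpty <- !is.na(v) & trimws(as.character(v)) != "" &
      toupper(trimws(as.character(v))) != "NA"
    num <- suppressWarnings(as.numeric(v))
    parseFailures <- parseFailures + sum(nonEmpty & is.na(num))
    out[[sid]] <- num
  }
  extra <- setdiff(names(raw),
                   c(unlist(.REQUIRED_COLUMNS), sampleCols))
  if (length(extra))
    message("ignoring ", length(extra), " unrecognized column(s): ",
            paste(utils::head(extra, 5), collapse = ", "))
  attr(out, "parse_failures") <- parseFailures
  out
}

#' Apply record-level peptide quality filters
#'
#' A record survives iff all of: nonempty master accession; `quan_info` not
#' `NoQuanValues`/`NoneMonoisotopic`; exactly one protein group; PSM
#' ambiguity `Unambiguous`; PEP <= 0.05; q-value <= 0.05.  Thresholds are
#' inclusive and label matching is case-insensitive.  Missing PEP/q-values
#' fail their filters (counted separately).  Each rule is counted
#' independently, so a record may contribute to several removal counts.
#'
#' @param records data.frame from [readPeptideTable()].
#' @param pepMax,qMax inclusive thresholds.
#' @return list with `records` (survivors, original row order) and `report`,
#'   a list of per-rule removal counts reconciling
#'   `surviving = input - |union removed|`.
#' @export
filterPeptides <- function(records, pepMax = 0.05, qMax = 0.05) {
  acc <- as.character(records$master_accession)
  badAccession <- is.na(acc) | trimws(acc) == ""
  flag <- tolower(trimws(as.character(records$quan_info)))
  badQuanInfo <- flag %in% c("noquanvalues", "nonemonoisotopic")
  badGroups <- is.na(records$n_protein_groups) |
    records$n_protein_groups != 1L
  badAmbiguity <- tolower(trimws(as.character(records$psm_ambiguity))) !=
    "unambiguous"
  pepMissing <- is.na(records$pep)
  qMissing <- is.na(records$q_value)
  badPep <- pepMissing | records$pep > pepMax
  badQ <- qMissing | records$q_value > qMax

  removed <- badAccession | badQuanInfo | badGroups | badAmbiguity |
    badPep | badQ
  report <- list(
    input = nrow(records),
    removed_missing_accession = sum(badAccession),
    removed_quan_flag = sum(badQuanInfo),
    removed_multi_group = sum(badGroups),
    removed_ambiguous_psm = sum(badAmbiguity),
    removed_pep = sum(badPep),
    removed_q_value = sum(badQ),
    pep_missing = sum(pepMissing),
    q_value_missing = sum(qMissing),
    removed_total = sum(removed),
    surviving = sum(!removed))
  if (report$surviving == 0L)
    warning("no peptide records survive the QC filters")
  out <- records[!removed, , drop = FALSE]
  attr(out, "parse_failures") <- attr(records, "parse_failures")
  list(records = out, report = report)
}

#' Assemble the peptide intensity matrix
#'
#' Builds a peptide x sample `SummarizedExperiment` (assay `intensity`, raw
#' scale) from surviving records.  Rows are keyed by (sequence, accession);
#' duplicate rows for the same key are summed (ion currents are additive),
#' with a cell left missing only when every contributing record is missing.
#' Column order follows the metadata.
#'
#' @param records surviving records from [filterPeptides()].
#' @param metadata sample metadata (`sample_id`, `organ`, `age_months`,
#'   `mouse_id`).
#' @return `SummarizedExperiment` with rowData `sequence`,
#'   `master_accession` and colData from `metadata`.
#' @export
buildIntensityMatrix <- function(records, metadata) {
  if (nrow(records) == 0L)
    stop("cannot build an intensity matrix from zero surviving records")
  sids <- metadata$sample_id
  if (!all(sids %in% names(records)))
    stop("records lack intensity columns for some metadata samples")
  key <- paste(records$sequence, records$master_accession, sep = "\r")
  grp <- factor(key, levels = unique(key))
  x <- as.matrix(records[, sids, drop = FALSE])
  obs <- rowsum((!is.na(x)) * 1L, grp)
  x[is.na(x)] <- 0
  tot <- rowsum(x, grp)
  ord <- match(levels(grp), rownames(tot))
  obs <- obs[ord, , drop = FALSE]
  tot <- tot[ord, , drop = FALSE]
  tot[obs == 0L] <- NA_real_
  first <- !duplicated(grp)
  rd <- S4Vectors::DataFrame(
    sequence = records$sequence[first],
    master_accession = records$master_accession[first])
  rownames(tot) <- key[first]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = tot), rowData = rd,
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id))
}
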