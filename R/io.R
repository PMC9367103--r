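#' Read a mutation observation table (TSV or minimal VCF)
#'
#' TSV dialect: tab-separated with columns `patient_id`, `timepoint`
#' (`pre`/`post_a`/`post_b`), `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene`, `effect`, `alt_reads`, `ref_reads`. VCF dialect: VCF 4.2 with
#' per-sample `AD` (ref,alt depths) in FORMAT and `GENE`/`EFFECT` INFO keys;
#' patient and timepoint are taken from the sample column name
#' `<patient>_<timepoint>`. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Data frame of mutation observations (TSV column schema).
#' @export
read_mutation_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") .read_mutation_tsv(path) else .read_mutation_vcf(path)
}

.mutation_cols <- c("patient_id", "timepoint", "chrom", "pos", "ref", "alt",
                    "gene", "effect", "alt_reads", "ref_reads")

.read_mutation_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("chrom" %in% names(d)) d$chrom <- as.character(d$chrom)
  missing_cols <- setdiff(.mutation_cols, names(d))
  if (length(missing_cols))
    stop("mutation table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("pos", "alt_reads", "ref_reads")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    d[[col]] <- as.integer(v)
  }
  bad <- which(d$alt_reads < 0 | d$ref_reads < 0 | d$pos < 1 |
                 is.na(d$alt_reads) | is.na(d$ref_reads) | is.na(d$pos))
  if (length(bad))
    stop("invalid counts/positions at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  d$mutation_id <- d$mutation_id %||%
    paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt, sep = ":")
  d
}

.read_mutation_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(v, "GENE")
  effect <- vcfR::extract.info(v, "EFFECT")
  ad <- vcfR::extract.gt(v, "AD")
  rows <- list()
  for (smp in colnames(ad)) {
    parts <- strsplit(smp, "_")[[1]]
    tp <- paste(parts[-1], collapse = "_")
    counts <- do.call(rbind, lapply(strsplit(ad[, smp], ","), as.integer))
    rows[[smp]] <- data.frame(
      patient_id = parts[1], timepoint = tp,
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      gene = as.character(gene), effect = as.character(effect),
      alt_reads = counts[, 2], ref_reads = counts[, 1],
      stringsAsFactors = FALSE
    )
  }
  d <- do.call(rbind, rows)
  d$mutation_id <- paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt, sep = ":")
  rownames(d) <- NULL
  d
}

#' Write a mutation observation table as TSV
#'
#' @param observations mutation observation data frame.
#' @param path output file.
#' @export
write_mutation_tsv <- function(observations, path) {
  cols <- intersect(c(.mutation_cols, "mutation_id"), names(observations))
  write.table(observations[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write one sample's observations as a minimal VCF 4.2
#'
#' One sample column named `<patient>_<timepoint>`, `AD` (ref,alt) in
#' FORMAT, `GENE` and `EFFECT` as INFO keys. Plain text, no compression.
#'
#' @param observations observations for a single patient/timepoint.
#' @param path output file.
#' @export
write_mutation_vcf <- function(observations, path) {
  stopifnot(length(unique(observations$patient_id)) == 1,
            length(unique(observations$timepoint)) == 1)
  smp <- paste(observations$patient_id[1], observations$timepoint[1], sep = "_")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", smp, sep = "\t")
  )
  o <- observations[order(observations$chrom, observations$pos), ]
  body <- paste(o$chrom, o$pos, ".", o$ref, o$alt, ".", "PASS",
                paste0("GENE=", o$gene, ";EFFECT=", o$effect),
                "AD", paste0(o$ref_reads, ",", o$alt_reads), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write BED-like segment tables
#'
#' Tab-separated, 0-based half-open intervals with columns `patient_id`,
#' `timepoint`, `chrom`, `start`, `end`, `n_major`, `n_minor` (an optional
#' `bin` label column is carried through).
#'
#' @param path file path.
#' @return `read_segments`: data frame of segments.
#' @export
read_segments <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("chrom" %in% names(d)) d$chrom <- as.character(d$chrom)
  req <- c("patient_id", "timepoint", "chrom", "start", "end",
           "n_major", "n_minor")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("segment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(d$end <= d$start)) stop("segments must have end > start")
  if (any(d$n_major < 0 | d$n_minor < 0)) stop("negative copy numbers")
  d
}

#' @rdname read_segments
#' @param segments segment data frame.
#' @export
write_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits `mutations.tsv` (all samples, long format), one minimal VCF per
#' sample under `vcf/`, `segments.tsv`, `purity.tsv`, and `truth.json`
#' (clonal trees, prevalences and mutation assignments, sufficient to score
#' recovery). Output is deterministic for a fixed simulation seed.
#'
#' @param cohort a `"sim_cohort"` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_mutation_tsv(cohort$observations, file.path(out_dir, "mutations.tsv"))
  by_sample <- split(cohort$observations,
                     paste(cohort$observations$patient_id,
                           cohort$observations$timepoint, sep = "_"))
  for (smp in names(by_sample))
    write_mutation_vcf(by_sample[[smp]],
                       file.path(out_dir, "vcf", paste0(smp, ".vcf")))
  write_segments(cohort$segments, file.path(out_dir, "segments.tsv"))
  write.table(cohort$purity, file.path(out_dir, "purity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- lapply(cohort$truth, function(tr) list(
    patient_id = tr$patient_id,
    clones = tr$tree$clones,
    prevalence = as.data.frame(cbind(subclone_id = seq_len(nrow(tr$tree$prevalence)),
                                     tr$tree$prevalence)),
    mutations = tr$tree$mutations[c("mutation_id", "subclone_id", "gene", "effect")]
  ))
  jsonlite::write_json(list(patients = truth), file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `observations`, `segments`, `purity`, and `truth`
#'   (`NULL` when no truth file is present).
#' @export
read_cohort <- function(dir) {
  obs <- read_mutation_table(file.path(dir, "mutations.tsv"), "tsv")
  seg <- read_segments(file.path(dir, "segments.tsv"))
  pur <- read.delim(file.path(dir, "purity.tsv"), stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::fromJSON(readLines(truth_path), simplifyVector = TRUE,
                       simplifyDataFrame = FALSE)$patients else NULL
  list(observations = obs, segments = seg, purity = pur, truth = truth)
}
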