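#' Construct a methylation dataset
#'
#' Bundles a beta-value matrix (probes x samples, values in \[0, 1\]), an
#' optional detection-p matrix of the same shape, and a sample sheet. The
#' sample sheet records, per array, the subject, the anatomical site
#' (`fimbrial` or `proximal`) and the group (`MUT` or `control`); subjects
#' with both sites present form the paired analysis set.
#'
#' @param beta Numeric matrix with unique probe-id rownames and sample-id
#'   colnames.
#' @param detection_p Optional numeric matrix, same dimnames as `beta`.
#' @param samples Data frame with columns `sample_id`, `subject_id`, `site`,
#'   `group`, one row per column of `beta`.
#' @return A list of class `meth_dataset`.
#' @export
meth_dataset <- function(beta, detection_p = NULL, samples) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("'beta' must be a numeric matrix")
  if (is.null(rownames(beta)) || anyDuplicated(rownames(beta)))
    stop("beta rownames must be unique probe ids")
  if (is.null(colnames(beta)) || anyDuplicated(colnames(beta)))
    stop("beta colnames must be unique sample ids")
  required <- c("sample_id", "subject_id", "site", "group")
  if (!all(required %in% names(samples)))
    stop("sample sheet must have columns: ", paste(required, collapse = ", "))
  if (!identical(sort(samples$sample_id), sort(colnames(beta))))
    stop("sample sheet ids do not match beta colnames")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$site %in% c("fimbrial", "proximal")))
    stop("sample 'site' must be 'fimbrial' or 'proximal'")
  if (anyDuplicated(samples[, c("subject_id", "site")]))
    stop("at most one sample per (subject, site) is allowed")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p must have the same shape as beta")
    dimnames(detection_p) <- dimnames(beta)
    rng <- range(detection_p, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("detection p-values must lie in [0, 1]")
  }
  structure(list(beta = beta, detection_p = detection_p, samples = samples),
            class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf("meth_dataset: %d probes x %d samples (%d subjects; detection p %s)\n",
              nrow(x$beta), ncol(x$beta), length(unique(x$samples$subject_id)),
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

## numeric TSVs are written at 6 significant digits, the declared text
## precision for round-tripping

#' Read / write a probe-by-sample numeric matrix as TSV
#'
#' First column `probe_id`, remaining columns one per sample. Values are
#' written at 6 significant digits.
#'
#' @param m Numeric matrix with probe-id rownames.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(signif(m, 6)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read / write the sample sheet
#' @param samples Sample-sheet data frame.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
}

#' Read / write the probe annotation
#'
#' Columns: `probe_id`, `chrom`, `pos` (1-based), `genes` (possibly empty,
#' `;`-separated symbols), `gene_relation`, `cgi_relation`.
#' @param annotation Annotation data frame.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(annotation, path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- as.data.frame(data.table::fread(path, sep = "\t"))
  ann$probe_id <- as.character(ann$probe_id)
  ann$genes <- as.character(ann$genes)
  ann$genes[is.na(ann$genes)] <- ""
  if (any(ann$pos < 1)) stop("annotation positions must be >= 1")
  ann
}

#' Write a full methylation dataset to a directory
#'
#' Emits `beta.tsv`, `detection_p.tsv` (when present) and `samples.tsv`.
#' @param dataset A [meth_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_meth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(dataset$beta, file.path(dir, "beta.tsv"))
  if (!is.null(dataset$detection_p))
    write_matrix_tsv(dataset$detection_p, file.path(dir, "detection_p.tsv"))
  write_sample_sheet(dataset$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' @rdname write_meth_dataset
#' @export
read_meth_dataset <- function(dir) {
  beta <- read_matrix_tsv(file.path(dir, "beta.tsv"))
  detp_path <- file.path(dir, "detection_p.tsv")
  detp <- if (file.exists(detp_path)) read_matrix_tsv(detp_path) else NULL
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  meth_dataset(beta, detp, samples)
}

#' Read / write gene sets in GMT format
#'
#' Reading delegates to [fgsea::gmtPathways()]. Writing emits the standard
#' `name<TAB>description<TAB>gene...` lines.
#' @param sets Named list of character vectors.
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read / write a BED peak track
#'
#' Standard 0-based half-open BED via rtracklayer; in-memory tracks are
#' 1-based closed [GenomicRanges::GRanges].
#' @param gr A `GRanges`.
#' @param path File path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}

#' Write / read a peak-track set with its manifest
#'
#' Each track is written as `<tissue>_<mark>.bed`; `manifest.tsv` maps
#' `file` to `tissue` and `mark`.
#' @param track_set A `peak_track_set`.
#' @param dir Directory for the BED files and manifest.
#' @export
write_peak_tracks <- function(track_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- track_set$manifest
  man$file <- paste0(gsub("[^A-Za-z0-9]+", "_", man$key), ".bed")
  for (i in seq_len(nrow(man)))
    write_bed(track_set$tracks[[man$key[i]]], file.path(dir, man$file[i]))
  data.table::fwrite(man[, c("file", "tissue", "mark")],
                     file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_peak_tracks
#' @export
read_peak_tracks <- function(dir) {
  man <- as.data.frame(data.table::fread(file.path(dir, "manifest.tsv"),
                                         sep = "\t"))
  man$key <- paste(man$tissue, man$mark, sep = "|")
  tracks <- lapply(seq_len(nrow(man)),
                   function(i) read_bed(file.path(dir, man$file[i])))
  names(tracks) <- man$key
  structure(list(tracks = tracks,
                 manifest = man[, c("tissue", "mark", "key")]),
            class = "peak_track_set")
}
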