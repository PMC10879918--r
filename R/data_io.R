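#' Read a gene-by-sample count matrix
#'
#' Reads a non-negative integer read-count matrix, either from a delimited
#' table (gene ids in the first column, sample ids in the header) or from a
#' matrix-market coordinate file with sidecar id lists (`<path>.genes` and
#' `<path>.samples`, one id per line).
#'
#' Counts tables are expected genes-in-rows (the TempO-Seq convention).  Set
#' `transpose = TRUE` for samples-in-rows input; orientation is never
#' guessed from the data.
#'
#' @param path path to the count file.
#' @param format `"delimited"` (tab- or comma-separated, autodetected from
#'   the header line) or `"matrix-market"`.
#' @param transpose logical; transpose the matrix after reading.
#' @return an integer matrix, genes in rows, with gene ids as rownames and
#'   sample ids as colnames, validated by [validate_counts()].
#' @seealso [write_counts()], [read_annotation()]
#' @export
read_counts <- function(path, format = c("delimited", "matrix-market"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (format == "delimited") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    if (ncol(tab) < 2L) stop("malformed header: expected gene id column ",
                             "followed by one column per sample")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- as.character(tab[[1L]])
  } else {
    sp <- Matrix::readMM(path)
    gfile <- paste0(path, ".genes")
    sfile <- paste0(path, ".samples")
    if (!file.exists(gfile) || !file.exists(sfile))
      stop("matrix-market counts need sidecar id lists '", gfile,
           "' and '", sfile, "'")
    m <- as.matrix(sp)
    gid <- readLines(gfile)
    sid <- readLines(sfile)
    if (length(gid) != nrow(m))
      stop("gene id sidecar has ", length(gid), " ids for ", nrow(m), " rows")
    if (length(sid) != ncol(m))
      stop("sample id sidecar has ", length(sid), " ids for ", ncol(m),
           " columns")
    dimnames(m) <- list(gid, sid)
  }
  if (transpose) m <- t(m)
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks that counts are a numeric matrix of non-negative integral values
#' with unique, non-empty gene and sample ids.  Returns the matrix in
#' integer storage mode; errors name the offending cell or id.
#'
#' @param counts numeric matrix, genes in rows.
#' @return the validated integer matrix.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  bad <- which(!is.finite(counts) | counts < 0 |
                 counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop("non-integer or negative count at gene '",
         rownames(counts)[i[1L]], "', sample '", colnames(counts)[i[2L]],
         "' (value ", counts[bad[1L]], ")")
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate gene id: '", dup[1L], "'")
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicate sample id: '", dup[1L], "'")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: delimited (tab-separated, gene ids in the
#' first column named `gene_id`) or matrix-market with sidecar id lists.
#'
#' @param counts integer matrix, genes in rows.
#' @param path output path.
#' @param format `"delimited"` or `"matrix-market"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path,
                         format = c("delimited", "matrix-market")) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "delimited") {
    tab <- data.frame(gene_id = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  }
  invisible(path)
}

ANNOTATION_COLS <- c("sample_id", "chemical", "concentration_uM", "time_h",
                     "bio_rep", "tech_rep", "plate", "well")

#' Read a sample annotation table
#'
#' Reads the delimited sample annotation with columns `sample_id`,
#' `chemical`, `concentration_uM`, `time_h`, `bio_rep`, `tech_rep`,
#' `plate`, `well`.  Rows with concentration exactly 0 are vehicle
#' controls; their `chemical` is set to `NA`.  Concentration is in
#' micromolar, time in hours; no unit strings are parsed.
#'
#' @param path path to a tab- or comma-delimited table.
#' @return a `data.frame`, one row per sample, with a logical
#'   `is_control` column appended.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Validate a sample annotation table
#'
#' @param ann data.frame with the columns listed under [read_annotation()].
#' @return the validated annotation with `is_control` appended.
#' @export
validate_annotation <- function(ann) {
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols))
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ann$sample_id <- as.character(ann$sample_id)
  ann$chemical <- as.character(ann$chemical)
  ann$concentration_uM <- as.numeric(ann$concentration_uM)
  ann$time_h <- as.numeric(ann$time_h)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id: '",
         ann$sample_id[duplicated(ann$sample_id)][1L], "'")
  bad <- which(!is.finite(ann$concentration_uM) | ann$concentration_uM < 0)
  if (length(bad))
    stop("negative or missing concentration for sample '",
         ann$sample_id[bad[1L]], "'")
  bad <- which(!is.finite(ann$time_h) | ann$time_h <= 0)
  if (length(bad))
    stop("non-positive or missing time_h for sample '",
         ann$sample_id[bad[1L]], "'")
  ann$is_control <- ann$concentration_uM == 0
  ann$chemical[ann$is_control] <- NA_character_
  ann
}

#' Write a sample annotation table
#'
#' @param ann annotation data.frame.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann[, ANNOTATION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe a concentration-time plate design
#'
#' Constructs the experimental-design description used by
#' [generate_design()] and [validate_design()].  Defaults mirror a 5
#' chemical x 8 concentration (dilution factor 2.5, top 50 uM; one
#' chemical topped at 10 uM) x 5 time point x 3 biological x 3 technical
#' replicate layout with 6 vehicle controls per 96-well plate and the 8
#' concentrations split 4 + 4 over 2 plates, 1980 samples in all.
#'
#' @param chemicals character vector of chemical names.
#' @param top_conc_uM named or unnamed numeric vector of top
#'   concentrations, recycled over `chemicals`.
#' @param n_conc number of concentrations per chemical.
#' @param dilution_factor ratio between consecutive concentrations.
#' @param time_points_h exposure times in hours.
#' @param n_bio_reps,n_tech_reps biological / technical replicates.
#' @param n_controls_per_plate vehicle controls on each plate.
#' @param n_plates_per_timepoint plates that split the dilution series.
#' @return an object of class `"experiment_design"`.
#' @export
experiment_design <- function(chemicals = c("aflatoxin B1",
                                            "benzo[a]pyrene",
                                            "cyclosporine A",
                                            "rotenone",
                                            "trichostatin A"),
                              top_conc_uM = c(50, 50, 50, 10, 50),
                              n_conc = 8L,
                              dilution_factor = 2.5,
                              time_points_h = c(2, 6, 12, 24, 48),
                              n_bio_reps = 3L,
                              n_tech_reps = 3L,
                              n_controls_per_plate = 6L,
                              n_plates_per_timepoint = 2L) {
  stopifnot(length(chemicals) >= 1L, n_conc >= 1L, dilution_factor > 1,
            all(time_points_h > 0), n_bio_reps >= 1L, n_tech_reps >= 1L,
            n_controls_per_plate >= 0L, n_plates_per_timepoint >= 1L,
            n_conc %% n_plates_per_timepoint == 0L)
  top <- rep_len(top_conc_uM, length(chemicals))
  conc <- lapply(top, function(x) x / dilution_factor^(seq_len(n_conc) - 1L))
  names(conc) <- chemicals
  structure(list(chemicals = chemicals,
                 concentrations_per_chemical = conc,
                 dilution_factor = dilution_factor,
                 time_points_h = sort(time_points_h),
                 n_conc = as.integer(n_conc),
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 n_controls_per_plate = as.integer(n_controls_per_plate),
                 n_plates_per_timepoint = as.integer(n_plates_per_timepoint)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Concentration-time experiment design\n")
  cat("  chemicals:       ", paste(x$chemicals, collapse = ", "), "\n")
  cat("  concentrations:  ", x$n_conc, " per chemical, dilution factor ",
      x$dilution_factor, "\n", sep = "")
  cat("  time points (h): ", paste(x$time_points_h, collapse = ", "), "\n")
  cat("  replicates:      ", x$n_bio_reps, "biological x", x$n_tech_reps,
      "technical\n")
  cat("  plates/timepoint:", x$n_plates_per_timepoint, "with",
      x$n_controls_per_plate, "vehicle controls each\n")
  cat("  total samples:   ", design_total_samples(x), "\n")
  invisible(x)
}

#' Closed-form sample total of a design
#'
#' `(n_chemicals x conc-per-plate x n_tech + n_controls) x n_plates x`
#' `n_timepoints x n_bio`, the plate-layout enumeration of the design.
#'
#' @param design an [experiment_design()].
#' @return integer sample count.
#' @export
design_total_samples <- function(design) {
  conc_per_plate <- design$n_conc / design$n_plates_per_timepoint
  per_plate <- length(design$chemicals) * conc_per_plate *
    design$n_tech_reps + design$n_controls_per_plate
  as.integer(per_plate * design$n_plates_per_timepoint *
               length(design$time_points_h) * design$n_bio_reps)
}

#' Check an annotation against a design
#'
#' Reports (never raises): the total sample count, the expected closed-form
#' total, a per-(chemical, concentration, time, bio_rep) completeness table
#' of technical-replicate counts, the design cells with no samples, and
#' whether every plate carries at least one vehicle control.
#'
#' @param ann sample annotation (see [read_annotation()]).
#' @param design an [experiment_design()].
#' @return a list of class `"design_report"` with elements `total`,
#'   `expected_total`, `cells`, `missing_cells`, `plates_without_controls`.
#' @export
validate_design <- function(ann, design) {
  ann <- validate_annotation(as.data.frame(ann))
  cells <- expand.grid(chemical = design$chemicals,
                       conc_rank = seq_len(design$n_conc),
                       time_h = design$time_points_h,
                       bio_rep = seq_len(design$n_bio_reps),
                       stringsAsFactors = FALSE)
  cells$concentration_uM <- mapply(
    function(ch, r) design$concentrations_per_chemical[[ch]][r],
    cells$chemical, cells$conc_rank)
  key <- function(ch, co, ti, bi)
    paste(ch, signif(co, 9), ti, bi, sep = "|")
  trt <- ann[!ann$is_control, , drop = FALSE]
  have <- table(key(trt$chemical, trt$concentration_uM, trt$time_h,
                    trt$bio_rep))
  k <- key(cells$chemical, cells$concentration_uM, cells$time_h,
           cells$bio_rep)
  cells$n_tech <- as.integer(have[k])
  cells$n_tech[is.na(cells$n_tech)] <- 0L
  plates <- unique(ann$plate)
  ctrl_plates <- unique(ann$plate[ann$is_control])
  structure(list(total = nrow(ann),
                 expected_total = design_total_samples(design),
                 cells = cells,
                 missing_cells = cells[cells$n_tech == 0L, , drop = FALSE],
                 plates_without_controls = setdiff(plates, ctrl_plates)),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report: ", x$total, " samples (expected ",
      x$expected_total, ")\n", sep = "")
  cat("  complete cells: ", sum(x$cells$n_tech > 0L), "/",
      nrow(x$cells), "\n", sep = "")
  if (nrow(x$missing_cells))
    cat("  missing cells:  ", nrow(x$missing_cells), "\n", sep = "")
  if (length(x$plates_without_controls))
    cat("  plates without vehicle controls: ",
        paste(x$plates_without_controls, collapse = ", "), "\n", sep = "")
  invisible(x)
}
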