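#' The rearranged Desikan-Killiany region table
#'
#' Returns the canonical 68-region cortical region table used throughout the
#' package: region ids 1..68 grouped by lobe (frontal 1-28, temporal 29-46,
#' parietal 47-60, occipital 61-68), with odd ids in the left hemisphere and
#' even ids in the right. This numbering fixes the row/column order of every
#' FD matrix and network downstream.
#'
#' @return A data.frame with columns `id`, `name`, `abbreviation`, `lobe`
#'   (one of `"frontal"`, `"temporal"`, `"parietal"`, `"occipital"`),
#'   `hemisphere` (`"L"` or `"R"`) and `label` (abbreviation_hemisphere,
#'   unique across the 68 rows).
#' @examples
#' rt <- dk_region_table()
#' table(rt$lobe)
#' @export
dk_region_table <- function() {
  frontal <- c(
    "Caudal anterior cingulate" = "CACg",
    "Caudal middle frontal"     = "CMF",
    "Lateral orbital frontal"   = "LOrF",
    "Medial orbital frontal"    = "MOrF",
    "Paracentral"               = "PaC",
    "Parsopercularis"           = "Op",
    "Parsorbitalis"             = "Or",
    "Parstriangularis"          = "Tr",
    "Precentral"                = "PreC",
    "Rostral anterior cingulate" = "RoACg",
    "Rostral middle frontal"    = "RoMF",
    "Superior frontal"          = "SF",
    "Frontal pole"              = "FPol",
    "Insula"                    = "Ins"
  )
  temporal <- c(
    "Bankssts"            = "B",
    "Entorhinal"          = "En",
    "Fusiform"            = "Fu",
    "Inferior temporal"   = "IT",
    "Medial temporal"     = "MT",
    "Para hippocampal"    = "PaH",
    "Superior temporal"   = "ST",
    "Temporal pole"       = "TPol",
    "Transverse temporal" = "TrT"
  )
  parietal <- c(
    "Inferior parietal"  = "IP",
    "Isthmus cingulate"  = "IstCg",
    "Postcentral"        = "PoC",
    "Posterior cingulate" = "PoCg",
    "Precuneus"          = "PreCu",
    "Superior parietal"  = "SP",
    "Supra marginal"     = "SM"
  )
  occipital <- c(
    "Cuneus"            = "Cu",
    "Lateral occipital" = "LO",
    "Lingual"           = "Lg",
    "Pericalcarine"     = "PerCa"
  )
  blocks <- list(frontal = frontal, temporal = temporal,
                 parietal = parietal, occipital = occipital)
  rows <- do.call(rbind, lapply(names(blocks), function(lb) {
    ab <- blocks[[lb]]
    data.frame(
      name = rep(names(ab), each = 2L),
      abbreviation = rep(unname(ab), each = 2L),
      lobe = lb,
      hemisphere = rep(c("L", "R"), times = length(ab)),
      stringsAsFactors = FALSE
    )
  }))
  rows$id <- seq_len(nrow(rows))
  rows$label <- paste(rows$abbreviation, rows$hemisphere, sep = "_")
  rt <- rows[, c("id", "name", "abbreviation", "lobe", "hemisphere", "label")]
  validate_region_table(rt)
}

#' Validate a region table
#'
#' Checks the invariants the pipeline relies on: exactly 68 rows with ids
#' 1..68, odd ids left / even ids right, known lobes with the fixed lobe
#' sizes (frontal 28, temporal 18, parietal 14, occipital 8), and unique
#' labels.
#'
#' @param rt a data.frame shaped like [dk_region_table()].
#' @return `rt`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_region_table <- function(rt) {
  required <- c("id", "name", "abbreviation", "lobe", "hemisphere", "label")
  if (!is.data.frame(rt) || !all(required %in% names(rt)))
    stop("region table must have columns ", paste(required, collapse = ", "))
  if (nrow(rt) != 68L)
    stop("region table must have exactly 68 rows, got ", nrow(rt))
  if (!identical(sort(as.integer(rt$id)), 1:68))
    stop("region ids must be exactly 1..68 with no duplicates")
  rt <- rt[order(rt$id), , drop = FALSE]
  rownames(rt) <- NULL
  expected_hemi <- ifelse(rt$id %% 2L == 1L, "L", "R")
  if (!identical(as.character(rt$hemisphere), expected_hemi))
    stop("hemisphere must be L for odd ids and R for even ids")
  sizes <- c(frontal = 28L, temporal = 18L, parietal = 14L, occipital = 8L)
  if (!all(rt$lobe %in% names(sizes)))
    stop("unknown lobe: ", paste(setdiff(unique(rt$lobe), names(sizes)), collapse = ", "))
  got <- table(factor(rt$lobe, levels = names(sizes)))
  if (!all(as.integer(got) == sizes))
    stop("lobe sizes must be frontal=28, temporal=18, parietal=14, occipital=8")
  if (anyDuplicated(rt$label))
    stop("region labels must be unique")
  rt
}

#' Read or write the region table as CSV
#'
#' @param path file path.
#' @return `load_region_table()` returns a validated region table;
#'   `write_region_table()` returns `path` invisibly.
#' @export
load_region_table <- function(path) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(rt)
}

#' @rdname load_region_table
#' @param rt a region table.
#' @export
write_region_table <- function(rt, path) {
  validate_region_table(rt)
  utils::write.csv(rt, path, row.names = FALSE)
  invisible(path)
}

#' Construct a labeled parcellation
#'
#' A labeled parcellation couples a 3D integer label grid (0 = background,
#' 1..68 = cortical regions) with its region table and voxel size.
#'
#' @param labels a 3D integer array with values in 0..68.
#' @param region_table a region table, default [dk_region_table()].
#' @param voxel_size_mm positive length-3 numeric, metadata only.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, region_table = dk_region_table(),
                         voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  lv <- as.vector(labels)
  if (any(lv != round(lv)))
    stop("parcellation labels must be integers")
  region_table <- validate_region_table(region_table)
  present <- sort(unique(lv[lv != 0]))
  bad <- setdiff(present, region_table$id)
  if (length(bad))
    stop("labels outside the region table: ", paste(bad, collapse = ", "))
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive numbers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, region_table = region_table,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "parcellation")
}

#' Read/write a labeled parcellation as NIfTI
#'
#' @param path path to a NIfTI file.
#' @inheritParams parcellation
#' @return `read_parcellation()` returns a `parcellation`;
#'   `write_parcellation()` returns `path` invisibly.
#' @export
read_parcellation <- function(path, region_table = dk_region_table()) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
  if (any(abs(arr - round(arr)) > 1e-6))
    stop("NIfTI volume does not hold integer labels")
  vox <- RNifti::pixdim(img)[1:3]
  parcellation(array(as.integer(round(arr)), dim = dim(arr)),
               region_table = region_table, voxel_size_mm = vox)
}

#' @rdname read_parcellation
#' @param parc a `parcellation`.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  img <- RNifti::asNifti(parc$labels)
  RNifti::pixdim(img) <- parc$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a cohort FD matrix
#'
#' Couples a subjects x 68 matrix of per-region fractal-dimension values
#' with its region table. Column order follows region id 1..68.
#'
#' @param values numeric matrix, one row per subject, 68 columns.
#' @param group_label character scalar naming the group.
#' @param subject_ids optional character vector of row ids.
#' @param region_table a region table.
#' @return An object of class `fd_cohort`.
#' @export
fd_cohort <- function(values, group_label = "group",
                      subject_ids = NULL, region_table = dk_region_table()) {
  region_table <- validate_region_table(region_table)
  values <- as.matrix(values)
  if (ncol(values) != nrow(region_table))
    stop("cohort matrix must have ", nrow(region_table), " columns, got ",
         ncol(values))
  if (!all(is.finite(values)))
    stop("cohort matrix contains missing or non-finite FD values")
  if (is.null(subject_ids))
    subject_ids <- sprintf("%s_%02d", group_label, seq_len(nrow(values)))
  colnames(values) <- region_table$label
  rownames(values) <- subject_ids
  structure(list(values = values, group_label = group_label,
                 subject_ids = subject_ids, region_table = region_table),
            class = "fd_cohort")
}

#' Read/write a cohort FD matrix as CSV
#'
#' Rows are subjects, columns the 68 region labels in atlas order; the
#' first column holds subject ids.
#'
#' @param path file path.
#' @inheritParams fd_cohort
#' @return `read_cohort()` returns an `fd_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path, group_label = "group",
                        region_table = dk_region_table()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    stop("cohort CSV must have a leading subject_id column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(vals), region_table$label))
    stop("cohort CSV columns must be the 68 region labels in atlas order")
  fd_cohort(vals, group_label = group_label, subject_ids = df$subject_id,
            region_table = region_table)
}

#' @rdname read_cohort
#' @param cohort an `fd_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fd_cohort"))
  df <- data.frame(subject_id = cohort$subject_ids,
                   cohort$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-subject regional FD from parcellation volumes
#'
#' Runs [region_fd()] on every region of every subject volume and stacks
#' the FD values into a cohort matrix. All 68 regions must be non-empty in
#' every subject.
#'
#' @param parcs a list of `parcellation` objects, or a character vector of
#'   NIfTI paths.
#' @param group_label group name attached to the resulting cohort.
#' @param region_table a region table.
#' @param ... passed on to [region_fd()] (e.g. `r_max`, `crop`).
#' @return An `fd_cohort` with one row per subject.
#' @export
cohort_from_parcellations <- function(parcs, group_label = "group",
                                      region_table = dk_region_table(), ...) {
  if (is.character(parcs))
    parcs <- lapply(parcs, read_parcellation, region_table = region_table)
  vals <- matrix(NA_real_, nrow = length(parcs), ncol = nrow(region_table))
  for (s in seq_along(parcs)) {
    parc <- parcs[[s]]
    if (!inherits(parc, "parcellation"))
      stop("element ", s, " is not a parcellation")
    for (j in region_table$id) {
      fit <- tryCatch(region_fd(parc, j, ...), error = function(e)
        stop("subject ", s, ", region ", j, " (",
             region_table$label[j], "): ", conditionMessage(e), call. = FALSE))
      vals[s, j] <- fit$fd
    }
  }
  fd_cohort(vals, group_label = group_label, region_table = region_table)
}
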