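#' Build a bank of high-resolution atlases
#'
#' An atlas is a triple (intensity volume, label map, six landmarks) on the
#' high-resolution lattice; a bank of such atlases is the unit of explicit
#' anatomical shape prior used by the refinement stage. Incomplete landmark
#' sets are rejected.
#'
#' @param cohort list of triples with elements `volume`, `labels`, `landmarks`
#'   (and optionally `id`), e.g. from [make_cohort()].
#' @param provenance character tag, `"phantom"` or `"network-predicted"`.
#' @return An `atlas_bank` object (list of atlas entries).
#' @export
build_atlas_bank <- function(cohort, provenance = "phantom") {
  entries <- lapply(seq_along(cohort), function(i) {
    it <- cohort[[i]]
    id <- if (!is.null(it$id)) it$id else sprintf("subject%03d", i)
    if (is.null(it$landmarks) || !inherits(it$landmarks, "landmark_set"))
      stop(sprintf("atlas '%s': missing landmark set", id))
    missing <- setdiff(landmark_names(), rownames(it$landmarks$voxel))
    if (length(missing))
      stop(sprintf("atlas '%s': missing landmark(s) %s", id,
                   paste(missing, collapse = ", ")))
    stopifnot(inherits(it$volume, "cmr_volume"), inherits(it$labels, "cmr_labelmap"))
    assert_same_lattice(it$volume, it$labels, sprintf("atlas '%s' volume/labels", id))
    list(id = id, volume = it$volume, labels = it$labels, landmarks = it$landmarks)
  })
  structure(entries, class = "atlas_bank", provenance = provenance)
}

#' @export
print.atlas_bank <- function(x, ...) {
  cat(sprintf("<atlas_bank> %d atlases (%s)\n", length(x), attr(x, "provenance")))
  invisible(x)
}

#' Append one atlas to a bank
#' @param bank an `atlas_bank`.
#' @param volume,labels,landmarks the new atlas triple.
#' @param id subject identifier.
#' @return The enlarged bank.
#' @export
append_atlas <- function(bank, volume, labels, landmarks, id = NULL) {
  stopifnot(inherits(bank, "atlas_bank"))
  if (is.null(id)) id <- sprintf("subject%03d", length(bank) + 1L)
  entry <- build_atlas_bank(list(list(volume = volume, labels = labels,
                                      landmarks = landmarks, id = id)),
                            provenance = attr(bank, "provenance"))[[1]]
  out <- c(unclass(bank), list(entry))
  structure(out, class = "atlas_bank", provenance = attr(bank, "provenance"))
}

#' Write / read an atlas bank as NIfTI + JSON + manifest
#'
#' Each atlas is persisted as `<id>_vol.nii.gz`, `<id>_lab.nii.gz` and
#' `<id>_lm.json`, with a `manifest.csv` listing the subject ids.
#'
#' @param bank an `atlas_bank`.
#' @param dir directory (created if needed).
#' @return `write_atlas_bank` returns `dir` invisibly; `read_atlas_bank`
#'   returns an `atlas_bank`.
#' @export
write_atlas_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "atlas_bank"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in bank) {
    write_volume(e$volume, file.path(dir, paste0(e$id, "_vol.nii.gz")))
    write_labelmap(e$labels, file.path(dir, paste0(e$id, "_lab.nii.gz")))
    write_landmarks(e$landmarks, file.path(dir, paste0(e$id, "_lm.json")))
  }
  manifest <- data.frame(id = vapply(bank, `[[`, "", "id"))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_atlas_bank
#' @export
read_atlas_bank <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  cohort <- lapply(manifest$id, function(id) {
    list(id = id,
         volume = read_volume(file.path(dir, paste0(id, "_vol.nii.gz"))),
         labels = read_labelmap(file.path(dir, paste0(id, "_lab.nii.gz"))),
         landmarks = read_landmarks(file.path(dir, paste0(id, "_lm.json"))))
  })
  build_atlas_bank(cohort)
}
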