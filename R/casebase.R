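#' Open or create a case store
#'
#' A portable, text-backed case database: a root directory holding
#' `users.json`, one JSON document per case under `cases/`, registered
#' classifiers under `classifiers/` and per-classifier 2D coordinates
#' under `coords/`. The layout mirrors the relational model of a
#' decision-support installation — users with administration rights,
#' cases owned by their uploader, spectra per TE class, clinical records,
#' shared case notes, and the stored (x, y) position of every case under
#' every classifier — while remaining diffable plain text.
#'
#' @param root directory path; created (with subdirectories) if absent.
#' @return a `case_store` handle.
#' @export
case_store <- function(root) {
  dir.create(file.path(root, "cases"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "classifiers"), showWarnings = FALSE)
  dir.create(file.path(root, "coords"), showWarnings = FALSE)
  users_path <- file.path(root, "users.json")
  if (!file.exists(users_path))
    jsonlite::write_json(list(), users_path, auto_unbox = TRUE)
  structure(list(root = root), class = "case_store")
}

.store_users <- function(store) {
  jsonlite::read_json(file.path(store$root, "users.json"))
}

.store_write_users <- function(store, users) {
  jsonlite::write_json(users, file.path(store$root, "users.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

.case_path <- function(store, case_id) {
  file.path(store$root, "cases", paste0(case_id, ".json"))
}

#' Register a user
#'
#' @param store a [case_store()].
#' @param username unique user name.
#' @param is_admin whether the user has administration rights (admins may
#'   edit any case).
#' @param preferences free-form display preferences (e.g. glyph colour
#'   and shape per class).
#' @return `username`, invisibly.
#' @export
add_user <- function(store, username, is_admin = FALSE, preferences = list()) {
  users <- .store_users(store)
  if (username %in% vapply(users, `[[`, "", "username"))
    .mrsdx_stop(sprintf("username '%s' already exists", username),
                "mrsdx_conflict")
  users[[length(users) + 1L]] <- list(username = username,
                                      is_admin = isTRUE(is_admin),
                                      preferences = preferences)
  .store_write_users(store, users)
  invisible(username)
}

.get_user <- function(store, username) {
  for (u in .store_users(store)) if (u$username == username) return(u)
  .mrsdx_stop(sprintf("unknown user '%s'", username), "mrsdx_not_found")
}

#' Build a case record
#'
#' @param case_id unique case identifier.
#' @param tissue_type diagnostic tissue-type label (the term covers
#'   tumour classes as well as non-tumour conditions and normal brain).
#' @param case_set one of `"reference"`, `"secondary"`, `"example"`,
#'   `"user"`.
#' @param spectra named list of [canonical_spectrum()] keyed by TE class
#'   (`short`, `long`).
#' @param clinical named list of clinical-record fields (age, sex,
#'   tumour location/size, radiological diagnosis, removal and biopsy
#'   flags, WHO classification, grading, outcomes, validation flags,
#'   assigned class, ...); all optional.
#' @param notes character vector of shared case notes.
#' @param images character vector of image file references.
#' @return list of class `case_record` (uploader is set by [add_case()]).
#' @export
case_record <- function(case_id, tissue_type = NA_character_,
                        case_set = c("user", "reference", "secondary", "example"),
                        spectra = list(), clinical = list(),
                        notes = character(), images = character()) {
  case_set <- match.arg(case_set)
  stopifnot(all(names(spectra) %in% c("short", "long", "other")))
  structure(list(case_id = as.character(case_id), uploader = NA_character_,
                 tissue_type = tissue_type, case_set = case_set,
                 spectra = spectra, clinical = clinical,
                 notes = as.character(notes), images = as.character(images)),
            class = "case_record")
}

.case_to_json <- function(case) {
  case$spectra <- lapply(case$spectra, function(s)
    list(intensities = s$intensities, te_class = s$te_class,
         provenance = s$provenance))
  class(case) <- NULL
  case
}

.case_from_json <- function(x) {
  x$spectra <- lapply(x$spectra, function(s)
    canonical_spectrum(unlist(s$intensities), te_class = s$te_class,
                       provenance = unlist(s$provenance)))
  x$notes <- as.character(unlist(x$notes))
  x$images <- as.character(unlist(x$images))
  structure(x, class = "case_record")
}

#' Add a case to the store
#'
#' The case becomes visible to every user of the installation; the
#' submitting user is recorded as uploader and is the only non-admin
#' allowed to edit it later.
#'
#' @param store a [case_store()].
#' @param case a [case_record()].
#' @param user username of the uploader (must be registered).
#' @return the case id, invisibly.
#' @export
add_case <- function(store, case, user) {
  stopifnot(inherits(case, "case_record"))
  .get_user(store, user)
  path <- .case_path(store, case$case_id)
  if (file.exists(path))
    .mrsdx_stop(sprintf("case id '%s' already exists", case$case_id),
                "mrsdx_conflict")
  case$uploader <- user
  jsonlite::write_json(.case_to_json(case), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null", na = "null")
  invisible(case$case_id)
}

#' Retrieve a case by id
#'
#' @param store a [case_store()].
#' @param case_id the case identifier.
#' @return the [case_record()].
#' @export
get_case <- function(store, case_id) {
  path <- .case_path(store, case_id)
  if (!file.exists(path))
    .mrsdx_stop(sprintf("case '%s' not found", case_id), "mrsdx_not_found")
  .case_from_json(jsonlite::read_json(path))
}

#' Edit a case
#'
#' Applies a patch of field updates. Non-note fields may only be changed
#' by the case's uploader or an administrator; any registered user may
#' append to the shared case notes via the special patch key `add_note`.
#'
#' @param store a [case_store()].
#' @param case_id the case identifier.
#' @param patch named list of replacement field values; the key
#'   `add_note` appends a note instead of replacing a field.
#' @param user username performing the edit.
#' @return the updated [case_record()], invisibly.
#' @export
edit_case <- function(store, case_id, patch, user) {
  u <- .get_user(store, user)
  case <- get_case(store, case_id)
  fields <- names(patch)
  restricted <- setdiff(fields, "add_note")
  if (length(restricted) > 0L &&
      !(identical(case$uploader, user) || isTRUE(u$is_admin)))
    .mrsdx_stop(sprintf(
      "user '%s' is not the uploader of case '%s'; only the uploader (or an admin) may edit it",
      user, case_id), "mrsdx_permission_error")
  for (f in restricted) {
    if (f %in% c("case_id", "uploader"))
      .mrsdx_stop(sprintf("field '%s' is immutable", f), "mrsdx_invalid_argument")
    case[[f]] <- patch[[f]]
  }
  if ("add_note" %in% fields)
    case$notes <- c(case$notes, sprintf("[%s] %s", user, patch$add_note))
  jsonlite::write_json(.case_to_json(case), .case_path(store, case_id),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null", na = "null")
  invisible(case)
}

#' Register a classifier in the store
#'
#' @param store a [case_store()].
#' @param classifier_id unique classifier identifier.
#' @param meta named list of metadata (TE mode, feature count, ...).
#' @return `classifier_id`, invisibly.
#' @export
register_classifier <- function(store, classifier_id, meta = list()) {
  jsonlite::write_json(c(list(classifier_id = classifier_id), meta),
                       file.path(store$root, "classifiers",
                                 paste0(classifier_id, ".json")),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(classifier_id)
}

#' Store per-case 2D coordinates for a classifier
#'
#' Persists the latent (x, y) position of each case under a registered
#' classifier, one row per (case, classifier); re-storing upserts.
#'
#' @param store a [case_store()].
#' @param classifier_id a classifier registered with
#'   [register_classifier()].
#' @param projections data.frame with columns `case_id`, `x`, `y`.
#' @return number of coordinate rows now stored for this classifier.
#' @export
store_coordinates <- function(store, classifier_id, projections) {
  if (!file.exists(file.path(store$root, "classifiers",
                             paste0(classifier_id, ".json"))))
    .mrsdx_stop(sprintf("classifier '%s' not registered", classifier_id),
                "mrsdx_not_found")
  stopifnot(all(c("case_id", "x", "y") %in% names(projections)))
  path <- file.path(store$root, "coords", paste0(classifier_id, ".json"))
  existing <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else
      data.frame(case_id = character(), x = numeric(), y = numeric())
  keep <- !(existing$case_id %in% as.character(projections$case_id))
  merged <- rbind(existing[keep, c("case_id", "x", "y")],
                  data.frame(case_id = as.character(projections$case_id),
                             x = projections$x, y = projections$y))
  merged <- merged[order(merged$case_id), ]
  jsonlite::write_json(merged, path, digits = I(17), pretty = TRUE)
  nrow(merged)
}

#' Read stored classifier coordinates
#'
#' @param store a [case_store()].
#' @param classifier_id the classifier.
#' @return data.frame with `case_id`, `x`, `y` ordered by case id.
#' @export
get_coordinates <- function(store, classifier_id) {
  path <- file.path(store$root, "coords", paste0(classifier_id, ".json"))
  if (!file.exists(path))
    .mrsdx_stop(sprintf("no coordinates stored for '%s'", classifier_id),
                "mrsdx_not_found")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' List cases in the store
#'
#' @param store a [case_store()].
#' @param case_set optional filter on the case set.
#' @param tissue_type optional filter on the tissue-type / superclass
#'   label.
#' @param te optional TE availability filter (`"short"`, `"long"`): keep
#'   only cases carrying a spectrum of that class.
#' @return data.frame of case summaries ordered by ascending case id.
#' @export
list_cases <- function(store, case_set = NULL, tissue_type = NULL, te = NULL) {
  files <- sort(list.files(file.path(store$root, "cases"), pattern = "\\.json$",
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    x <- jsonlite::read_json(f)
    data.frame(case_id = x$case_id,
               uploader = if (is.null(x$uploader)) NA_character_ else x$uploader,
               tissue_type = if (is.null(x$tissue_type)) NA_character_ else x$tissue_type,
               case_set = x$case_set,
               te_available = paste(sort(names(x$spectra)), collapse = "+"),
               n_notes = length(x$notes))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), uploader = character(),
               tissue_type = character(), case_set = character(),
               te_available = character(), n_notes = integer())
  if (!is.null(case_set)) out <- out[out$case_set %in% case_set, ]
  if (!is.null(tissue_type)) out <- out[out$tissue_type %in% tissue_type, ]
  if (!is.null(te))
    out <- out[vapply(strsplit(out$te_available, "+", fixed = TRUE),
                      function(v) all(te %in% v), logical(1)), ]
  out[order(out$case_id), , drop = FALSE]
}
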