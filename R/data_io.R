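#' Construct a species-by-plot incidence/abundance matrix
#'
#' The basic data unit: non-negative integer counts of each species in each
#' survey plot of one habitat (unlogged, naturally disturbed forest or the
#' salvage-logged portion of the same disturbance). Any count greater than
#' zero is treated downstream as an occurrence; abundances are reduced to
#' incidence before analysis.
#'
#' @param counts Integer matrix (species x plots), or a data frame with a
#'   `species` first column followed by one column per plot.
#' @param species_ids,plot_ids Character labels; taken from dimnames / column
#'   names when `NULL`.
#' @param habitat_label `"unlogged"` or `"logged"`.
#' @return An object of class `species_plot_matrix`: a list with elements
#'   `counts` (integer matrix with dimnames), and `habitat_label`.
#' @export
species_plot_matrix <- function(counts, species_ids = NULL, plot_ids = NULL,
                                habitat_label = c("unlogged", "logged")) {
  habitat_label <- match.arg(habitat_label)
  if (is.data.frame(counts)) {
    sp_col <- counts[[1L]]
    m <- as.matrix(counts[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(sp_col)
    counts <- m
  }
  if (!is.matrix(counts)) stop("`counts` must be a matrix or data frame.")
  if (!is.null(species_ids)) rownames(counts) <- species_ids
  if (!is.null(plot_ids)) colnames(counts) <- plot_ids
  if (is.null(rownames(counts))) {
    rownames(counts) <- if (nrow(counts)) paste0("sp", seq_len(nrow(counts))) else character()
  }
  if (is.null(colnames(counts))) colnames(counts) <- paste0("plot", seq_len(ncol(counts)))
  validate_species_plot_matrix(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, habitat_label = habitat_label),
            class = "species_plot_matrix")
}

validate_species_plot_matrix <- function(counts) {
  if (ncol(counts) < 1L) stop("A species-by-plot matrix needs at least one plot.")
  if (anyDuplicated(rownames(counts)))
    stop("Duplicated species labels: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("Duplicated plot labels: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("Counts contain missing values.")
  if (any(counts < 0)) stop("Counts must be non-negative.")
  if (any(counts != round(counts)))
    stop("Counts must be integers; fractional values are rejected, not rounded.")
  invisible(counts)
}

#' @export
print.species_plot_matrix <- function(x, ...) {
  cat(sprintf("<species_plot_matrix> %s habitat: %d species x %d plots\n",
              x$habitat_label, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.species_plot_matrix <- function(x) dim(x$counts)

#' Read a species-by-plot matrix from CSV
#'
#' Accepts either a wide table (first column `species`, remaining columns are
#' plot ids, integer cells) or a long table with columns
#' `species, plot, count`; the layout is autodetected from the header. Cells
#' absent from a long table are zeros.
#'
#' @param path Path to a CSV file.
#' @param habitat_label `"unlogged"` or `"logged"`.
#' @return A [species_plot_matrix()].
#' @export
read_species_matrix <- function(path, habitat_label = c("unlogged", "logged")) {
  habitat_label <- match.arg(habitat_label)
  if (!file.exists(path)) stop("File not found: ", path)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  if (anyDuplicated(hdr))
    stop("Duplicated plot labels in header of ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal")
  if (identical(tolower(hdr), c("species", "plot", "count"))) {
    m <- long_to_matrix(df)
  } else {
    if (tolower(hdr[1]) != "species")
      stop("Expected first column `species` (wide) or columns ",
           "`species,plot,count` (long) in ", path)
    if (anyDuplicated(df[[1]]))
      stop("Duplicated species labels in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  species_plot_matrix(m, habitat_label = habitat_label)
}

long_to_matrix <- function(df) {
  names(df) <- tolower(names(df))
  if (anyDuplicated(df[, c("species", "plot")]))
    stop("Duplicated (species, plot) pairs in long-format input.")
  wide <- tidyr::pivot_wider(df, names_from = "plot", values_from = "count",
                             values_fill = 0)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- as.character(wide$species)
  m
}

#' Write a species-by-plot matrix to wide CSV
#'
#' Inverse of [read_species_matrix()] for the wide layout; a written matrix
#' re-reads to identical counts.
#'
#' @param x A [species_plot_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_matrix <- function(x, path) {
  stopifnot(inherits(x, "species_plot_matrix"))
  df <- tibble::as_tibble(x$counts, rownames = "species")
  readr::write_csv(df, path)
  invisible(path)
}

#' Study metadata for one paired dataset
#'
#' @param dataset_id,study_id,taxon_group Character labels. Several datasets
#'   (taxa, survey years) may share one `study_id`.
#' @param saproxylic Logical; whether the taxon depends on dead wood.
#' @param disturbance_type One of `"fire"`, `"windstorm"`, `"insect_outbreak"`.
#' @param years_since_disturbance Non-negative number of years between the
#'   natural disturbance and the survey; values above 100 are rejected as
#'   implausible.
#' @return A one-row tibble of class `study_metadata`.
#' @export
study_metadata <- function(dataset_id, study_id, taxon_group, saproxylic,
                           disturbance_type, years_since_disturbance) {
  disturbance_type <- as.character(disturbance_type)
  if (!disturbance_type %in% c("fire", "windstorm", "insect_outbreak"))
    stop("`disturbance_type` must be fire, windstorm or insect_outbreak, got: ",
         disturbance_type)
  years_since_disturbance <- as.numeric(years_since_disturbance)
  if (is.na(years_since_disturbance) || years_since_disturbance < 0 ||
      years_since_disturbance > 100)
    stop("`years_since_disturbance` must be in [0, 100], got: ",
         years_since_disturbance)
  out <- tibble::tibble(
    dataset_id = as.character(dataset_id),
    study_id = as.character(study_id),
    taxon_group = as.character(taxon_group),
    saproxylic = as.logical(saproxylic),
    disturbance_type = disturbance_type,
    years_since_disturbance = years_since_disturbance
  )
  class(out) <- c("study_metadata", class(out))
  out
}

#' Read a metadata table for a collection of paired datasets
#'
#' Expected columns: `dataset_id, study_id, taxon_group, saproxylic,
#' disturbance_type, years_since_disturbance, unlogged_file, logged_file`.
#' Rows failing the sanity bounds are dropped with a warning naming the
#' reason, mirroring screening rather than silent repair.
#'
#' @param path CSV path.
#' @return A tibble with one row per retained dataset and an attribute
#'   `excluded` (tibble of dropped rows with a `reason` column).
#' @export
read_metadata <- function(path) {
  req <- c("dataset_id", "study_id", "taxon_group", "saproxylic",
           "disturbance_type", "years_since_disturbance",
           "unlogged_file", "logged_file")
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("Metadata file lacks columns: ", paste(missing, collapse = ", "))
  df$saproxylic <- as.logical(df$saproxylic)
  bad_dist <- !df$disturbance_type %in% c("fire", "windstorm", "insect_outbreak")
  bad_year <- is.na(df$years_since_disturbance) |
    df$years_since_disturbance < 0 | df$years_since_disturbance > 100
  reason <- dplyr::case_when(
    bad_dist ~ "unknown disturbance_type",
    bad_year ~ "years_since_disturbance outside [0, 100]",
    TRUE ~ NA_character_
  )
  excluded <- dplyr::mutate(df[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  if (nrow(excluded))
    warning(sprintf("Excluded %d metadata row(s): %s", nrow(excluded),
                    paste(unique(excluded$reason), collapse = "; ")))
  keep <- df[is.na(reason), , drop = FALSE]
  attr(keep, "excluded") <- excluded
  keep
}

#' Reduce a species-by-plot matrix to incidence frequencies
#'
#' The incidence frequency Q_i of species i is the number of plots where it
#' was detected (count > 0); it is the analysis-scale summary used throughout
#' (occurrence among plots serves as the abundance proxy, being less
#' sensitive to within-plot clustering of individuals). Species never
#' detected are dropped.
#'
#' @param matrix A [species_plot_matrix()].
#' @return An object of class `incidence_freq`: list with `T` (number of
#'   plots), `Q` (named integer vector of frequencies, all in 1..T), `S_obs`,
#'   `Q1` and `Q2` (numbers of species seen in exactly one / two plots).
#' @export
to_incidence <- function(matrix) {
  stopifnot(inherits(matrix, "species_plot_matrix"))
  Tn <- ncol(matrix$counts)
  Q <- rowSums(matrix$counts > 0L)
  Q <- Q[Q > 0]
  incidence_freq(Tn, Q)
}

incidence_freq <- function(T, Q) {
  Q <- as.integer(Q) |> setNames(names(Q))
  stopifnot(T >= 1L, all(Q >= 1L), all(Q <= T))
  structure(
    list(T = as.integer(T), Q = Q, S_obs = length(Q),
         Q1 = sum(Q == 1L), Q2 = sum(Q == 2L)),
    class = "incidence_freq"
  )
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat(sprintf("<incidence_freq> T = %d plots, S_obs = %d, Q1 = %d, Q2 = %d\n",
              x$T, x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

#' @export
tidy.incidence_freq <- function(x, ...) {
  tibble::tibble(species = names(x$Q), frequency = unname(x$Q))
}

#' Pair an unlogged and a logged matrix into one analysis unit
#'
#' Merges the two species universes by exact label (species absent from one
#' habitat get frequency zero there) and attaches study metadata. Plot ids
#' must not overlap between habitats. A dataset with no species unique to the
#' unlogged sample is valid but flagged, since its retention benchmark is
#' undefined.
#'
#' @param unlogged,logged [species_plot_matrix()] objects with the matching
#'   habitat labels.
#' @param meta A [study_metadata()] row.
#' @return An object of class `paired_dataset`: list with `unlogged`,
#'   `logged`, `meta`, and `incidence` — a tibble with one row per pooled
#'   species and columns `species, q_unlogged, q_logged`.
#' @export
pair_datasets <- function(unlogged, logged, meta) {
  stopifnot(inherits(unlogged, "species_plot_matrix"),
            inherits(logged, "species_plot_matrix"))
  if (unlogged$habitat_label != "unlogged" || logged$habitat_label != "logged")
    stop("Habitat labels do not match the argument roles.")
  overlap <- intersect(colnames(unlogged$counts), colnames(logged$counts))
  if (length(overlap))
    stop("Plot ids occur in both habitats: ", paste(overlap, collapse = ", "))
  iu <- to_incidence(unlogged)
  il <- to_incidence(logged)
  species <- union(names(iu$Q), names(il$Q))
  inc <- tibble::tibble(
    species = species,
    q_unlogged = unname(iu$Q[species]) |> tidyr::replace_na(0L),
    q_logged = unname(il$Q[species]) |> tidyr::replace_na(0L)
  )
  if (!any(inc$q_unlogged > 0 & inc$q_logged == 0))
    warning("Dataset ", meta$dataset_id,
            " has no species unique to the unlogged sample; ",
            "its retention benchmark will be undefined.")
  structure(list(unlogged = unlogged, logged = logged, meta = meta,
                 incidence = inc),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "<paired_dataset> %s: T1 = %d unlogged, T2 = %d logged plots, %d pooled species\n",
    x$meta$dataset_id, ncol(x$unlogged$counts), ncol(x$logged$counts),
    nrow(x$incidence)))
  invisible(x)
}

n_plots_unlogged <- function(paired) ncol(paired$unlogged$counts)
n_plots_logged <- function(paired) ncol(paired$logged$counts)

#' Load a full collection of paired datasets from a metadata table
#'
#' @param metadata Tibble from [read_metadata()] (or with the same columns).
#' @param data_dir Directory against which `unlogged_file` / `logged_file`
#'   are resolved.
#' @return A named list of [pair_datasets()] objects, keyed by `dataset_id`.
#' @export
load_collection <- function(metadata, data_dir = ".") {
  purrr::pmap(metadata, function(dataset_id, study_id, taxon_group, saproxylic,
                                 disturbance_type, years_since_disturbance,
                                 unlogged_file, logged_file, ...) {
    pair_datasets(
      read_species_matrix(file.path(data_dir, unlogged_file), "unlogged"),
      read_species_matrix(file.path(data_dir, logged_file), "logged"),
      study_metadata(dataset_id, study_id, taxon_group, saproxylic,
                     disturbance_type, years_since_disturbance)
    )
  }) |> setNames(metadata$dataset_id)
}
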