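#' lamhier: cortical hierarchy from the laminar origin of projections
#'
#' Tools for quantifying the hierarchical organization of cortex from
#' retrograde-tracer data.  The central quantity is the SLN, the fraction of
#' supragranular labeled neurons of a source-to-target projection, which acts
#' as a proxy for hierarchical distance: values near 1 mark feedforward (FF)
#' pathways, values near 0 feedback (FB) pathways.  Hierarchical levels are
#' estimated by maximum likelihood under a beta-binomial model with a probit
#' link on the incidence matrix of the cortical graph
#' (\code{\link{fit_hierarchy_betabin}}), with a least-squares identity-link
#' alternative (\code{\link{fit_hierarchy_linear}}).  Supporting analyses:
#' pairwise SLN correlations between injections
#' (\code{\link{sln_correlation_matrix}}), weight-distance rules
#' (\code{\link{fit_distance_rule}}, \code{\link{fit_fln_sln_parabola}},
#' \code{\link{incidence_by_distance}}), laminar depth-profile splits
#' (\code{\link{fit_depth_split}}) and a seeded synthetic-data generator
#' (\code{\link{simulate_tracing}}).
#'
#' @name lamhier-package
#' @keywords internal
"_PACKAGE"

# ---- connectivity tables -----------------------------------------------------

#' Construct a validated connectivity table
#'
#' A connectivity table is a data frame of projection records, one row per
#' source-to-target pathway (optionally per injection replicate), with columns
#' \code{target}, \code{source}, and at least one of \code{supra}/\code{infra}
#' (non-negative laminar neuron counts) or \code{sln} (fraction in [0, 1]).
#' Optional columns: \code{fln} (fraction of labeled neurons, a connection
#' weight), \code{distance_mm} (white-matter distance between area centers)
#' and \code{replicate} (injection label).  SLN is always held internally as a
#' fraction; percentages are converted at the I/O boundary.
#'
#' @param records data frame with the columns described above.
#' @param compute_sln if \code{TRUE} (default), fill missing \code{sln} from
#'   counts as \code{supra / (supra + infra)}.
#' @return An object of class \code{connectivity_table} (a data frame) with an
#'   \code{areas} attribute listing every area named in the records.
#' @export
connectivity_table <- function(records, compute_sln = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("target", "source")
  if (!all(need %in% names(records)))
    stop("records must have 'target' and 'source' columns")
  records$target <- trimws(as.character(records$target))
  records$source <- trimws(as.character(records$source))
  for (col in c("supra", "infra", "sln", "fln", "distance_mm"))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  if (!"replicate" %in% names(records)) records$replicate <- NA_character_

  has_counts <- !is.na(records$supra) & !is.na(records$infra)
  if (compute_sln) {
    tot <- records$supra + records$infra
    fill <- has_counts & is.na(records$sln) & tot > 0
    records$sln[fill] <- records$supra[fill] / tot[fill]
  }
  tab <- structure(records,
                   class = c("connectivity_table", "data.frame"),
                   areas = sort(unique(c(records$target, records$source))))
  validate_connectivity(tab)
  tab
}

#' Validate a connectivity table
#'
#' Checks the structural invariants of a \code{\link{connectivity_table}}:
#' no self-projections, non-negative counts, SLN and FLN within [0, 1],
#' SLN consistent with counts where both are present, positive distances,
#' and uniqueness of (target, source, replicate) triples.
#'
#' @param tab a \code{connectivity_table}.
#' @return \code{tab}, invisibly; errors describe the first violation found.
#' @export
validate_connectivity <- function(tab) {
  if (nrow(tab) == 0) return(invisible(tab))
  if (any(tab$target == tab$source))
    stop("self-projection (source == target) in row ",
         which(tab$target == tab$source)[1])
  cnt <- c(tab$supra, tab$infra)
  if (any(!is.na(cnt) & (cnt < 0 | cnt != floor(cnt))))
    stop("laminar counts must be non-negative integers")
  # rows with neither counts nor SLN are retained (e.g. a pathway whose
  # laminar origin could not be measured) but are unusable for SLN analyses
  has_counts <- !is.na(tab$supra) & !is.na(tab$infra)
  bad <- !is.na(tab$sln) & (tab$sln < 0 | tab$sln > 1)
  if (any(bad))
    stop("SLN out of [0, 1] in row ", which(bad)[1],
         " (percentages must be converted to fractions)")
  chk <- has_counts & !is.na(tab$sln) & (tab$supra + tab$infra) > 0
  if (any(chk)) {
    implied <- tab$supra[chk] / (tab$supra[chk] + tab$infra[chk])
    if (any(abs(implied - tab$sln[chk]) > 1e-6))
      stop("SLN inconsistent with counts in row ",
           which(chk)[which(abs(implied - tab$sln[chk]) > 1e-6)[1]])
  }
  if (any(!is.na(tab$fln) & (tab$fln <= 0 | tab$fln > 1)))
    stop("FLN must lie in (0, 1]")
  if (any(!is.na(tab$distance_mm) & tab$distance_mm <= 0))
    stop("distances must be positive")
  key <- paste(tab$target, tab$source, tab$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (target, source, replicate) in row ",
         which(duplicated(key))[1])
  stopifnot(all(c(tab$target, tab$source) %in% attr(tab, "areas")))
  invisible(tab)
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat("Connectivity table: ", nrow(x), " projections over ",
      length(attr(x, "areas")), " areas (",
      length(unique(x$target)), " injected targets)\n", sep = "")
  cat("SLN present for ", sum(!is.na(x$sln)), " projections",
      if (any(!is.na(x$fln))) paste0("; FLN for ", sum(!is.na(x$fln))),
      if (any(!is.na(x$distance_mm)))
        paste0("; distance for ", sum(!is.na(x$distance_mm))),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# column-name dictionary for the delimited format
.io_cols <- c(TARGET = "target", SOURCE = "source", SUPRA = "supra",
              INFRA = "infra", SLN = "sln", FLN = "fln",
              DISTANCE_MM = "distance_mm", REPLICATE = "replicate")

#' Read a connectivity table from delimited text
#'
#' Reads a UTF-8 delimited file (tab or comma, auto-detected from the header
#' unless \code{sep} is given) with a header row naming at least
#' \code{TARGET}, \code{SOURCE} and one of (\code{SUPRA}, \code{INFRA}) or
#' \code{SLN}.  Optional columns: \code{FLN}, \code{DISTANCE_MM},
#' \code{REPLICATE}.  The literal \code{NA} denotes a missing value.  SLN is
#' given in percent in files and stored as a fraction.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs comma.
#' @param sln_unit unit of the SLN column in the file: \code{"percent"}
#'   (default, divided by 100 on read) or \code{"fraction"}.
#' @return a \code{\link{connectivity_table}}.
#' @export
read_connectivity <- function(path, sep = NULL,
                              sln_unit = c("percent", "fraction")) {
  sln_unit <- match.arg(sln_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           na.strings = "NA", check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           fileEncoding = "UTF-8")
  names(raw) <- trimws(toupper(names(raw)))
  unknown <- setdiff(names(raw), names(.io_cols))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  if (!all(c("TARGET", "SOURCE") %in% names(raw)))
    stop("header must name TARGET and SOURCE")
  if (!("SLN" %in% names(raw) ||
        all(c("SUPRA", "INFRA") %in% names(raw))))
    stop("header must name SLN or both SUPRA and INFRA")
  out <- list()
  for (up in names(raw)) {
    col <- raw[[up]]
    if (up %in% c("TARGET", "SOURCE", "REPLICATE")) {
      out[[.io_cols[[up]]]] <- trimws(col)
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("malformed value '", col[bad[1]], "' in column ", up,
             ", line ", bad[1] + 1L)
      out[[.io_cols[[up]]]] <- num
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!is.null(out$sln) && sln_unit == "percent")
    out$sln <- out$sln / 100
  connectivity_table(out)
}

#' Write a connectivity table to delimited text
#'
#' Inverse of \code{\link{read_connectivity}}: SLN is serialized in percent,
#' missing values as the literal \code{NA}, and only the columns that carry
#' any data are written.  \code{read_connectivity(write_connectivity(tab))}
#' reproduces \code{tab} field for field.
#'
#' @param tab a \code{\link{connectivity_table}}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_connectivity <- function(tab, path, sep = "\t") {
  validate_connectivity(tab)
  out <- data.frame(TARGET = tab$target, SOURCE = tab$source,
                    stringsAsFactors = FALSE)
  if (any(!is.na(tab$supra))) out$SUPRA <- tab$supra
  if (any(!is.na(tab$infra))) out$INFRA <- tab$infra
  if (any(!is.na(tab$sln)))   out$SLN <- round(tab$sln * 100, 6)
  if (any(!is.na(tab$fln)))   out$FLN <- tab$fln
  if (any(!is.na(tab$distance_mm))) out$DISTANCE_MM <- tab$distance_mm
  if (any(!is.na(tab$replicate)))   out$REPLICATE <- tab$replicate
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# ---- packaged fixtures -------------------------------------------------------

#' Published SLN and distance table for 11 injected macaque areas
#'
#' Returns the packaged transcription of the published table of pooled SLN
#' percentages and white-matter distances for every source area labeled by
#' injections in the 11 target areas V1, V2, V4, DP, MT, TEpd, TEO, STPc,
#' 8L, 8m and 7A.  Rows with an unmeasurable SLN are retained with
#' \code{sln = NA}.  No neuron counts and no FLN values are published in this
#' table; see \code{\link{fit_hierarchy}} for fitting from SLN-only data.
#'
#' @return a \code{\link{connectivity_table}} with 628 records.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_sln_distance.tsv",
                      package = "lamhier", mustWork = TRUE)
  read_connectivity(path, sep = "\t", sln_unit = "percent")
}

#' Source areas with an analog in the discrete-level reference hierarchy
#'
#' The 40 source areas whose projections are retained when comparing against
#' the classical discrete-level (Felleman-Van Essen type) hierarchy of visual
#' cortex.  Names match the spellings of the packaged SLN/distance table
#' exactly (\code{"PERIRHINAL"}, \code{"ENTORHINAL"}); the combined
#' \code{"TH/TF"} label used for some projections matches neither \code{"TH"}
#' nor \code{"TF"} of this list, and such rows are excluded by exact-name
#' filters.
#'
#' @return character vector of 40 area names.
#' @export
load_fve_sources <- function() {
  path <- system.file("extdata", "fve_sources.txt",
                      package = "lamhier", mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Named area sets used across the analyses
#'
#' \code{"fve"}: the 40-area source list of \code{\link{load_fve_sources}};
#' \code{"targets11"}: the 11 injected target areas;
#' \code{"ventral7"}: the five ventral-stream areas plus MT and DP that show
#' the most consistent pairwise hierarchical relation.
#'
#' @param name one of \code{"fve"}, \code{"targets11"}, \code{"ventral7"}.
#' @return character vector of area names.
#' @export
area_set <- function(name = c("fve", "targets11", "ventral7")) {
  switch(match.arg(name),
         fve = load_fve_sources(),
         targets11 = c("V1", "V2", "V4", "DP", "MT", "TEpd", "TEO",
                       "STPc", "8L", "8m", "7A"),
         ventral7 = c("V1", "V2", "V4", "TEO", "TEpd", "MT", "DP"))
}
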