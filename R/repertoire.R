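#' Construct a TCR repertoire sample
#'
#' A repertoire sample is a table of unique clonotypes (CDR3 identifiers)
#' with raw read/template counts, together with the metadata shared by all
#' downstream analyses: subject, time point and biological compartment.
#' Duplicate clonotype identifiers are aggregated by summing their counts;
#' zero-count rows are dropped (the underlying model describes observed
#' clonotypes only) and their number is reported via a message when
#' \code{quiet = FALSE}. Clonotype frequencies \eqn{p_i = f_i / F} are
#' computed over the retained rows, where \eqn{F} is the read depth
#' (sum of all counts).
#'
#' @param ids character vector of clonotype identifiers (typically CDR3
#'   nucleotide sequences, or amino-acid sequences when nucleotide
#'   sequences are unavailable).
#' @param counts integer vector of raw read/template counts, same length
#'   as \code{ids}.
#' @param subject,timepoint,compartment sample metadata labels.
#' @param sample_id label identifying this sample within a study; defaults
#'   to \code{subject.timepoint} (plus compartment when given).
#' @param threshold the minimum-count filter already applied to this
#'   table (1 for unfiltered data).
#' @param quiet suppress the dropped-zero-row message.
#'
#' @return An object of class \code{"tcr_repertoire"}: a list with
#'   elements \code{tab} (data frame with columns \code{clonotype_id},
#'   \code{count}, \code{frequency}, ordered by descending count with
#'   ties broken by identifier), \code{n_unique}, \code{read_depth},
#'   \code{subject}, \code{timepoint}, \code{compartment},
#'   \code{sample_id} and \code{threshold}.
#' @examples
#' rep <- tcr_repertoire(c("CASSL", "CASSQ", "CASSF"), c(10, 5, 5))
#' rep$read_depth   # 20
#' rep$tab$frequency
#' @export
tcr_repertoire <- function(ids, counts, subject = NA_character_,
                           timepoint = NA_character_,
                           compartment = NA_character_,
                           sample_id = NULL, threshold = 1L,
                           quiet = TRUE) {
  if (length(ids) != length(counts)) {
    stop_usage("'ids' and 'counts' must have equal length")
  }
  ids <- as.character(ids)
  if (anyNA(ids)) stop_usage("clonotype identifiers must not be NA")
  if (!is_count_vector(counts)) {
    bad <- which(!is.finite(counts) | counts < 0 |
                   abs(counts - round(counts)) >= 1e-8)[1]
    stop_usage("counts must be non-negative integers (offending row %d: %s)",
               bad, format(counts[bad]))
  }
  counts <- round(counts)
  zero <- counts == 0
  if (any(zero)) {
    if (!quiet) message(sum(zero), " zero-count row(s) dropped")
    ids <- ids[!zero]
    counts <- counts[!zero]
  }
  if (length(ids) == 0L) {
    stop_usage("empty sample: no clonotypes with positive count")
  }
  if (anyDuplicated(ids)) {
    agg <- rowsum(counts, ids)
    ids <- rownames(agg)
    counts <- as.numeric(agg[, 1])
  }
  ord <- order(-counts, ids)
  ids <- ids[ord]
  counts <- counts[ord]
  depth <- sum(counts)
  if (is.null(sample_id)) {
    sample_id <- paste(stats::na.omit(c(subject, timepoint, compartment)),
                       collapse = ".")
    if (sample_id == "") sample_id <- "sample"
  }
  out <- list(
    tab = data.frame(clonotype_id = ids, count = counts,
                     frequency = counts / depth,
                     stringsAsFactors = FALSE),
    n_unique = length(ids),
    read_depth = depth,
    subject = subject,
    timepoint = timepoint,
    compartment = compartment,
    sample_id = sample_id,
    threshold = as.integer(threshold)
  )
  class(out) <- "tcr_repertoire"
  out
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire sample '%s'\n", x$sample_id))
  meta <- c(subject = x$subject, timepoint = x$timepoint,
            compartment = x$compartment)
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  cat(sprintf("  %d unique clonotypes, read depth %s, min count %d\n",
              x$n_unique, format(x$read_depth, big.mark = ","),
              x$threshold))
  cat("  top clonotypes:\n")
  print(utils::head(x$tab, 5), row.names = FALSE)
  invisible(x)
}

#' @export
summary.tcr_repertoire <- function(object, ...) {
  c(n_unique = object$n_unique, read_depth = object$read_depth,
    max_frequency = max(object$tab$frequency),
    singleton_fraction = mean(object$tab$count == 1))
}

# Column-name candidates for the supported table dialects. ImmunoSEQ export
# headers vary by pipeline version, so several spellings are accepted.
.dialect_defaults <- list(
  generic = list(id = c("clonotype_id", "id", "clone_id"),
                 count = c("count", "reads", "templates")),
  immunoseq = list(
    nucleotide = c("nucleotide", "rearrangement", "nucleotide_cdr3",
                   "cdr3_rearrangement"),
    aminoacid = c("aminoAcid", "amino_acid", "aminoacid", "cdr3_amino_acid"),
    count = c("count (templates/reads)", "count_templates_reads", "templates",
              "count (reads)", "count", "reads")),
  airr = list(nucleotide = "junction", aminoacid = "junction_aa",
              count = "duplicate_count")
)

.pick_column <- function(header, candidates, field, required = TRUE) {
  hit <- candidates[candidates %in% header]
  if (length(hit) == 0L) {
    if (required) {
      stop_usage(
        "no column found for field '%s' (looked for: %s); supply column_map",
        field, paste(candidates, collapse = ", "))
    }
    return(NULL)
  }
  hit[1]
}

#' Read a clonotype count table
#'
#' Reads one tab-separated clonotype table into a validated
#' \code{\link{tcr_repertoire}}. Three dialects are supported:
#' \describe{
#'   \item{\code{generic}}{two columns, \code{clonotype_id} and
#'     \code{count}.}
#'   \item{\code{immunoseq}}{ImmunoSEQ-style exports carrying a
#'     nucleotide CDR3 column, an amino-acid CDR3 column and a
#'     template/read count column; several header spellings are
#'     recognized and can be overridden with \code{column_map}.}
#'   \item{\code{airr}}{AIRR Rearrangement TSV with \code{junction} /
#'     \code{junction_aa} identifier fields and \code{duplicate_count}.}
#' }
#' Clonotypes are keyed on the nucleotide CDR3 sequence when present
#' (the finer identifier), falling back to the amino-acid sequence;
#' \code{id_key = "aminoacid"} forces amino-acid keying, which merges
#' synonymous rearrangements. Rows sharing an identifier are summed and
#' zero-count rows are dropped.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect one of \code{"generic"}, \code{"immunoseq"},
#'   \code{"airr"}.
#' @param column_map optional named list overriding the column lookup:
#'   entries \code{id} (generic) or \code{nucleotide} / \code{aminoacid},
#'   and \code{count}.
#' @param id_key \code{"nucleotide"} (default) or \code{"aminoacid"}.
#' @param subject,timepoint,compartment,sample_id metadata passed to
#'   \code{\link{tcr_repertoire}}.
#' @param quiet suppress the dropped-zero-row message.
#' @return A \code{\link{tcr_repertoire}}.
#' @export
read_clonotype_table <- function(path,
                                 dialect = c("generic", "immunoseq", "airr"),
                                 column_map = NULL,
                                 id_key = c("nucleotide", "aminoacid"),
                                 subject = NA_character_,
                                 timepoint = NA_character_,
                                 compartment = NA_character_,
                                 sample_id = NULL, quiet = TRUE) {
  dialect <- match.arg(dialect)
  id_key <- match.arg(id_key)
  if (!file.exists(path)) stop_usage("input file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  defaults <- .dialect_defaults[[dialect]]
  map <- defaults
  for (nm in names(column_map)) map[[nm]] <- column_map[[nm]]
  header <- names(df)

  if (dialect == "generic") {
    id_col <- .pick_column(header, map$id, "id")
  } else {
    # nucleotide key preferred, amino-acid fallback
    if (id_key == "nucleotide") {
      id_col <- .pick_column(header, map$nucleotide, "nucleotide",
                             required = FALSE)
      if (is.null(id_col)) {
        id_col <- .pick_column(header, map$aminoacid, "aminoacid")
      }
    } else {
      id_col <- .pick_column(header, map$aminoacid, "aminoacid")
    }
  }
  count_col <- .pick_column(header, map$count, "count")

  counts <- df[[count_col]]
  if (is.character(counts)) {
    counts_num <- suppressWarnings(as.numeric(counts))
    if (anyNA(counts_num)) {
      stop_usage("non-numeric count at row %d of %s",
                 which(is.na(counts_num))[1], path)
    }
    counts <- counts_num
  }
  if (!is_count_vector(counts)) {
    bad <- which(!is.finite(counts) | counts < 0 |
                   abs(counts - round(counts)) >= 1e-8)[1]
    stop_usage("non-integer or negative count at row %d of %s", bad, path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  tcr_repertoire(df[[id_col]], counts, subject = subject,
                 timepoint = timepoint, compartment = compartment,
                 sample_id = sample_id, quiet = quiet)
}

#' Write a repertoire in canonical normalized form
#'
#' Writes the three-column canonical TSV (\code{clonotype_id},
#' \code{count}, \code{frequency}) so that tables round-trip through
#' \code{\link{read_clonotype_table}} with \code{dialect = "generic"}.
#'
#' @param x a \code{\link{tcr_repertoire}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_clonotype_table <- function(x, path) {
  stopifnot(inherits(x, "tcr_repertoire"))
  utils::write.table(x$tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a repertoire by minimum clonotype count
#'
#' Retains clonotypes with \code{count >= min_count} and recomputes
#' frequencies, read depth and richness over the retained rows, mirroring
#' how count-threshold robustness analyses recalculate clone frequency
#' after filtering.
#'
#' @param x a \code{\link{tcr_repertoire}}.
#' @param min_count minimum retained count (>= 1).
#' @return A filtered \code{\link{tcr_repertoire}} whose
#'   \code{threshold} records \code{min_count}.
#' @export
filter_by_count <- function(x, min_count) {
  stopifnot(inherits(x, "tcr_repertoire"))
  assert_scalar_number(min_count, "min_count", lower = 1)
  keep <- x$tab$count >= min_count
  if (!any(keep)) {
    stop_usage(
      "filtering sample '%s' at min_count = %d removes every clonotype",
      x$sample_id, as.integer(min_count))
  }
  tcr_repertoire(x$tab$clonotype_id[keep], x$tab$count[keep],
                 subject = x$subject, timepoint = x$timepoint,
                 compartment = x$compartment, sample_id = x$sample_id,
                 threshold = as.integer(min_count))
}

#' Presence/absence bookkeeping for a sample pair within a universe
#'
#' Consolidates the clonotypes present in any sample of \code{universe}
#' and tabulates, for the pair \code{(a, b)}: \code{n1} and \code{n2}
#' (clones present in each), \code{n12} (present in both) and \code{d12}
#' (absent in both but present elsewhere in the universe). These are the
#' inputs of the binary similarity measures (\code{\link{jaccard_index}},
#' \code{\link{bub_index}}); the negative-match term \code{d12} only
#' exists relative to a declared universe, typically all samples of one
#' subject.
#'
#' @param a,b the two \code{\link{tcr_repertoire}} samples compared.
#' @param universe list of \code{tcr_repertoire} objects declaring the
#'   clone universe; must contain both \code{a} and \code{b} (matched by
#'   \code{sample_id}). Defaults to the pair itself, in which case
#'   \code{d12 = 0} by construction.
#' @return An object of class \code{"tcr_presence"} with fields
#'   \code{universe_size}, \code{n1}, \code{n2}, \code{n12}, \code{d12}.
#' @examples
#' s1 <- tcr_repertoire(letters[1:5], rep(1, 5), sample_id = "s1")
#' s2 <- tcr_repertoire(c("a", "b", "c", "x"), rep(1, 4), sample_id = "s2")
#' presence_summary(s1, s2)   # pair universe: d12 = 0
#' @export
presence_summary <- function(a, b, universe = list(a, b)) {
  stopifnot(inherits(a, "tcr_repertoire"), inherits(b, "tcr_repertoire"))
  if (length(universe) == 0L) stop_usage("universe must be nonempty")
  uni_ids <- vapply(universe, function(s) s$sample_id, character(1))
  if (!(a$sample_id %in% uni_ids) || !(b$sample_id %in% uni_ids)) {
    stop_usage("both pair members must belong to the universe sample set")
  }
  all_clones <- unique(unlist(lapply(universe,
                                     function(s) s$tab$clonotype_id)))
  ia <- a$tab$clonotype_id
  ib <- b$tab$clonotype_id
  n12 <- length(intersect(ia, ib))
  n1 <- length(ia)
  n2 <- length(ib)
  out <- list(universe_size = length(all_clones),
              n1 = n1, n2 = n2, n12 = n12,
              d12 = length(all_clones) - (n1 + n2 - n12),
              pair = c(a$sample_id, b$sample_id))
  class(out) <- "tcr_presence"
  out
}

#' @export
print.tcr_presence <- function(x, ...) {
  cat(sprintf(
    "presence summary (%s vs %s): universe %d | n1 %d, n2 %d, n12 %d, d12 %d\n",
    x$pair[1], x$pair[2], x$universe_size, x$n1, x$n2, x$n12, x$d12))
  invisible(x)
}

#' Assemble a clonotype-by-sample count matrix for one subject
#'
#' Rows are the union of clonotype identifiers across the samples
#' (sorted), columns are the samples; a clonotype absent from a sample
#' gets count 0, so each column sum equals that sample's read depth.
#' This matrix is the substrate of the differential test
#' (\code{\link{run_difftest}}).
#'
#' @param samples list of >= 2 \code{\link{tcr_repertoire}} objects from
#'   the same subject.
#' @return An integer matrix with clonotype rownames and sample-id
#'   colnames; the subject is attached as attribute \code{"subject"}.
#' @export
to_count_matrix <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop_usage("need at least two samples")
  }
  stopifnot(all(vapply(samples, inherits, logical(1), "tcr_repertoire")))
  subs <- unique(vapply(samples, function(s) s$subject, character(1)))
  if (length(subs) > 1L) {
    stop_usage("samples mix subjects (%s); build one matrix per subject",
               paste(subs, collapse = ", "))
  }
  ids <- sort(unique(unlist(lapply(samples,
                                   function(s) s$tab$clonotype_id))))
  mat <- matrix(0L, nrow = length(ids), ncol = length(samples),
                dimnames = list(ids, vapply(samples,
                                            function(s) s$sample_id,
                                            character(1))))
  for (j in seq_along(samples)) {
    tab <- samples[[j]]$tab
    mat[tab$clonotype_id, j] <- as.integer(tab$count)
  }
  attr(mat, "subject") <- subs
  mat
}

#' Read a study manifest
#'
#' A manifest maps clonotype table files to their metadata. Two formats
#' are accepted: a TSV with columns \code{file}, \code{sample_id},
#' \code{subject}, \code{timepoint}, \code{compartment} and optionally
#' \code{dialect}; or a YAML file with a top-level \code{samples} list
#' whose entries carry the same fields.
#'
#' @param path manifest path (\code{.yaml}/\code{.yml} or TSV).
#' @return A data frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_usage("manifest not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    entries <- if (!is.null(y$samples)) y$samples else y
    if (!length(entries)) stop_usage("manifest %s lists no samples", path)
    rows <- lapply(entries, function(e) {
      data.frame(file = e$file,
                 sample_id = e$sample_id %||% NA_character_,
                 subject = e$subject %||% NA_character_,
                 timepoint = e$timepoint %||% NA_character_,
                 compartment = e$compartment %||% NA_character_,
                 dialect = e$dialect %||% "generic",
                 stringsAsFactors = FALSE)
    })
    man <- do.call(rbind, rows)
  } else {
    man <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"file" %in% names(man)) {
      stop_usage("manifest %s lacks the required 'file' column", path)
    }
    for (col in c("sample_id", "subject", "timepoint", "compartment")) {
      if (!col %in% names(man)) man[[col]] <- NA_character_
    }
    if (!"dialect" %in% names(man)) man$dialect <- "generic"
  }
  man
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load all samples of a study from a manifest
#'
#' @param manifest a manifest path or the data frame returned by
#'   \code{\link{read_manifest}}.
#' @param base_dir directory against which relative file paths are
#'   resolved; defaults to the manifest's directory (or the working
#'   directory when a data frame is given).
#' @return An object of class \code{"tcr_study"}: a list with
#'   \code{samples} (named list of \code{\link{tcr_repertoire}}) and
#'   \code{grouping} (subject -> ordered sample ids).
#' @export
load_study <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$file[i]
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(base_dir, f)
    sid <- manifest$sample_id[i]
    samples[[i]] <- read_clonotype_table(
      f, dialect = manifest$dialect[i],
      subject = manifest$subject[i], timepoint = manifest$timepoint[i],
      compartment = manifest$compartment[i],
      sample_id = if (is.na(sid)) NULL else sid)
  }
  names(samples) <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(names(samples))) {
    stop_usage("duplicate sample ids in manifest: %s",
               paste(unique(names(samples)[duplicated(names(samples))]),
                     collapse = ", "))
  }
  grouping <- split(names(samples),
                    vapply(samples, function(s) s$subject, character(1)))
  structure(list(samples = samples, grouping = grouping),
            class = "tcr_study")
}

#' @export
print.tcr_study <- function(x, ...) {
  cat(sprintf("TCR study: %d sample(s), %d subject(s)\n",
              length(x$samples), length(x$grouping)))
  for (sub in names(x$grouping)) {
    cat(sprintf("  %s: %s\n", sub,
                paste(x$grouping[[sub]], collapse = ", ")))
  }
  invisible(x)
}
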