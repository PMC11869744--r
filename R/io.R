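#' Write allele profiles and their genome-length sidecar as TSV
#'
#' One row per covered site: `sample_id`, `species_id`, `scaffold`,
#' `position` (0-based), `A`, `C`, `G`, `T`. The sidecar holds
#' `species_id`, `scaffold`, `length`; scaffolds are concatenated in
#' sidecar order to form per-genome coordinates.
#'
#' @param profiles list of [allele_profile()]s.
#' @param path output TSV path.
#' @param lengths_path sidecar TSV path.
#' @export
write_allele_profiles <- function(profiles, path, lengths_path) {
  rows <- lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, species_id = p$species_id,
               scaffold = "genome", position = p$pos,
               A = p$counts[, 1L], C = p$counts[, 2L],
               G = p$counts[, 3L], T = p$counts[, 4L],
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- unique(do.call(rbind, lapply(profiles, function(p)
    data.frame(species_id = p$species_id, scaffold = "genome",
               length = p$genome_length, stringsAsFactors = FALSE))))
  utils::write.table(gl, lengths_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Shared validator/assembler for site tables already in data.frame form.
# `line` gives the original file line of each row for error messages.
.profiles_from_sites <- function(tab, lengths, line) {
  need <- c("sample_id", "species_id", "scaffold", "position",
            "A", "C", "G", "T")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "))
  lk <- paste(lengths$species_id, lengths$scaffold, sep = "\x1f")
  if (anyDuplicated(lk)) stop("duplicate species/scaffold in lengths sidecar")
  # concatenated coordinates: per species, scaffold offsets in sidecar order
  offs <- stats::setNames(numeric(length(lk)), lk)
  tot <- list()
  for (i in seq_len(nrow(lengths))) {
    sid <- lengths$species_id[i]
    offs[lk[i]] <- tot[[sid]] %||% 0
    tot[[sid]] <- (tot[[sid]] %||% 0) + lengths$length[i]
  }
  rk <- paste(tab$species_id, tab$scaffold, sep = "\x1f")
  bad <- which(!(rk %in% lk))
  if (length(bad))
    stop("unknown species/scaffold at line ", line[bad[1L]], ": ",
         tab$species_id[bad[1L]], "/", tab$scaffold[bad[1L]])
  cnt <- as.matrix(tab[, c("A", "C", "G", "T")])
  bad <- which(rowSums(is.na(cnt)) > 0 | rowSums(cnt < 0) > 0)
  if (length(bad))
    stop("negative or missing base count at line ", line[bad[1L]])
  sclen <- stats::setNames(lengths$length, lk)
  bad <- which(is.na(tab$position) | tab$position < 0 |
               tab$position >= sclen[rk])
  if (length(bad))
    stop("position outside scaffold at line ", line[bad[1L]],
         " (position ", tab$position[bad[1L]], ")")
  gpos <- tab$position + offs[rk]
  glen <- vapply(tot, identity, 0)
  key <- paste(tab$sample_id, tab$species_id, sep = "\x1f")
  idx <- split(seq_len(nrow(tab)), key)
  lapply(idx, function(ii) {
    allele_profile(tab$sample_id[ii[1L]], tab$species_id[ii[1L]],
                   glen[[tab$species_id[ii[1L]]]],
                   pos = gpos[ii], counts = cnt[ii, , drop = FALSE])
  })
}

#' Read allele profiles from TSV
#'
#' Inverse of [write_allele_profiles()]. Malformed rows (unknown species or
#' scaffold, negative counts, positions beyond the scaffold) abort with the
#' offending file line number.
#'
#' @param path profile TSV.
#' @param lengths_path genome-length sidecar TSV (`species_id`, `scaffold`,
#'   `length`).
#' @return List of [allele_profile()]s (empty for an empty file).
#' @export
read_allele_profiles <- function(path, lengths_path) {
  lengths <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list())
  unname(.profiles_from_sites(tab, lengths, line = seq_len(nrow(tab)) + 1L))
}

#' Ingest an inStrain-style SNV table as allele profiles
#'
#' Maps a per-sample SNV/site table in the profiler dialect — columns
#' `scaffold`, `position` (0-based) and per-base counts `A`, `C`, `G`, `T`,
#' with the scaffold-to-genome assignment supplied by the sidecar — onto
#' [allele_profile()] objects for one sample. Sites absent from the table
#' are treated as uncovered, so such tables should contain every site
#' intended to be comparable, not only variant sites.
#'
#' @param path site table TSV.
#' @param sample_id sample the table belongs to.
#' @param lengths_path sidecar TSV with `species_id`, `scaffold`, `length`.
#' @return List of [allele_profile()]s.
#' @export
read_instrain_snvs <- function(path, sample_id, lengths_path) {
  lengths <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list())
  sc2sp <- stats::setNames(lengths$species_id, lengths$scaffold)
  if (!"species_id" %in% names(tab)) tab$species_id <- sc2sp[tab$scaffold]
  tab$sample_id <- sample_id
  unname(.profiles_from_sites(tab, lengths, line = seq_len(nrow(tab)) + 1L))
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `host_id`, `date` (ISO-8601) and
#' optionally `group`, `role`, `timepoint`, `designated_donor`.
#'
#' @param path TSV path.
#' @return data.frame with `date` parsed to Date and missing optional
#'   columns filled with defaults.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "host_id", "date")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  md$date <- tryCatch(as.Date(md$date), error = function(e) NA)
  if (anyNA(md$date)) stop("unparseable date in metadata")
  if (!"group" %in% names(md)) md$group <- NA_character_
  if (!"role" %in% names(md)) md$role <- "none"
  if (!"timepoint" %in% names(md)) md$timepoint <- "none"
  if (!"designated_donor" %in% names(md)) md$designated_donor <- NA_character_
  md
}

#' Pipeline configuration
#'
#' One structured object holding every threshold of the pipeline. The
#' `"standard"` preset is the published default set: presence at 25%
#' breadth with 5x depth, strain identity at 99.999% popANI, allele
#' detection at 2 reads and 5% frequency, 1000 permutations.
#'
#' @param preset `"standard"` or `"custom"` (label only).
#' @param min_depth,min_breadth,ani_threshold,min_count,min_freq thresholds.
#' @param n_perm permutations for enrichment tests.
#' @param seed default seed.
#' @param design `"fmt"` or `"social"` (used by [run_pipeline()]).
#' @param paths named list of input/output paths (optional).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "standard",
                            min_depth = 5L, min_breadth = 0.25,
                            ani_threshold = 0.99999,
                            min_count = 2L, min_freq = 0.05,
                            n_perm = 1000L, seed = 1L,
                            design = c("fmt", "social"),
                            paths = list()) {
  design <- match.arg(design)
  cfg <- list(preset = preset, min_depth = as.integer(min_depth),
              min_breadth = min_breadth, ani_threshold = ani_threshold,
              min_count = as.integer(min_count), min_freq = min_freq,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              design = design, paths = paths)
  if (cfg$min_depth < 1L || cfg$min_count < 1L || cfg$n_perm < 1L)
    stop("min_depth, min_count and n_perm must be positive")
  if (cfg$min_breadth < 0 || cfg$min_breadth > 1 ||
      cfg$ani_threshold < 0 || cfg$ani_threshold > 1 ||
      cfg$min_freq < 0 || cfg$min_freq > 1)
    stop("fractional thresholds must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> preset %s (%s design): depth >= %d, ",
                     "breadth >= %g, popANI >= %g, alleles >= %d reads / %g ",
                     "freq, %d permutations, seed %d\n"),
              x$preset, x$design, x$min_depth, x$min_breadth,
              x$ani_threshold, x$min_count, x$min_freq, x$n_perm, x$seed))
  invisible(x)
}
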