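#' Specification of a planted-motif synthetic dataset
#'
#' Describes a benchmark dataset in which negatives are i.i.d. draws from a
#' background base composition and positives additionally carry a wildcard
#' motif (e.g. `"U.AAU"`; '.' positions stay background) written near the
#' candidate site with probability `plant_prob`, at an offset jittered
#' uniformly within `offset_jitter` of the centre.  With `plant_prob = 0`
#' positives are statistically indistinguishable from negatives (the
#' no-signal null).
#'
#' @param n_pos,n_neg class sizes.
#' @param length window length `L` (default 41 nt, the most common window
#'   among published site predictors).
#' @param motif wildcard pattern over `{A,C,G,U,.}` (default `"U.AAU"`).
#' @param plant_prob probability a positive receives the motif.
#' @param offset_jitter uniform jitter radius (nt) around the centre.
#' @param composition background base frequencies for A, C, G, U.
#' @param seed integer seed.
#' @param name dataset name.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L, length = 41L,
                           motif = "U.AAU", plant_prob = 1.0,
                           offset_jitter = 3L,
                           composition = c(A = 0.25, C = 0.25,
                                           G = 0.25, U = 0.25),
                           seed = 7L, name = "synthetic") {
  motif <- toupper(motif)
  if (grepl("[^ACGU.]", motif)) stop2("motif must be over {A,C,G,U,.}")
  if (plant_prob < 0 || plant_prob > 1) stop2("plant_prob must be in [0, 1]")
  w <- nchar(motif)
  if (length < w + 2L * offset_jitter) {
    stop2("window length must be at least motif width + 2 * offset_jitter")
  }
  if (abs(sum(composition) - 1) > 1e-8 || any(composition < 0)) {
    stop2("composition must be nonnegative and sum to 1")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), motif = motif,
                 plant_prob = plant_prob,
                 offset_jitter = as.integer(offset_jitter),
                 composition = composition, seed = as.integer(seed),
                 name = name),
            class = "synthetic_spec")
}

#' Generate a planted-motif dataset
#'
#' Draws the dataset described by a [synthetic_spec()], fully seeded.  The
#' ground truth (whether and where each positive received the motif) is
#' returned as a sidecar table -- and written as a separate TSV by
#' [write_synthetic()] -- so it can never leak into the sequence data.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a [seq_dataset()]) and `truth` (data frame
#'   `id`, `planted`, `start`; `start` is the 0-based motif start or `NA`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- c("A", "C", "G", "U")
  L <- spec$length
  w <- nchar(spec$motif)
  motif_chars <- strsplit(spec$motif, "")[[1]]
  literal <- which(motif_chars != ".")
  site <- L %/% 2L
  center_start <- site - w %/% 2L  # 0-based start putting the motif centre on the site
  with_seed(spec$seed, {
    n <- spec$n_pos + spec$n_neg
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(bases, L, replace = TRUE, prob = spec$composition),
            collapse = "")
    }, character(1))
    planted <- logical(n)
    start <- rep(NA_integer_, n)
    for (i in seq_len(spec$n_pos)) {
      if (stats::runif(1) >= spec$plant_prob) next
      off <- sample.int(2L * spec$offset_jitter + 1L, 1L) -
        spec$offset_jitter - 1L
      s0 <- min(max(center_start + off, 0L), L - w)  # 0-based
      chars <- strsplit(seqs[i], "")[[1]]
      chars[s0 + literal] <- motif_chars[literal]
      seqs[i] <- paste(chars, collapse = "")
      planted[i] <- TRUE
      start[i] <- s0
    }
    ids <- c(sprintf("%s_pos_%04d", spec$name, seq_len(spec$n_pos)),
             sprintf("%s_neg_%04d", spec$name, seq_len(spec$n_neg)))
    ds <- seq_dataset(id = ids, sequence = seqs,
                      label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
                      name = spec$name)
    list(dataset = ds,
         truth = data.frame(id = ids, planted = planted, start = start,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a family of pseudo-species datasets
#'
#' One dataset per named motif: entries sharing a motif emulate
#' within-taxonomy conservation of the modification's sequence determinant,
#' distinct motifs emulate across-taxonomy divergence.  Used by the
#' cross-species transfer experiments.
#'
#' @param base_spec a [synthetic_spec()] providing sizes, length, jitter,
#'   composition and base seed.
#' @param motif_map named character vector mapping pseudo-species name to
#'   its planted motif, at least two entries.
#' @return Named list of `generate_dataset()` results.
#' @export
generate_species_family <- function(base_spec, motif_map) {
  if (length(motif_map) < 2L) stop2("motif_map needs at least two entries")
  if (is.null(names(motif_map)) || anyDuplicated(names(motif_map))) {
    stop2("motif_map must have unique names")
  }
  out <- lapply(seq_along(motif_map), function(i) {
    spec <- base_spec
    spec$motif <- toupper(motif_map[[i]])
    spec$name <- names(motif_map)[i]
    spec$seed <- derive_seed(base_spec$seed, 50L + i)
    generate_dataset(spec)
  })
  names(out) <- names(motif_map)
  out
}

#' Write a synthetic dataset with its ground truth and spec echo
#'
#' Emits FASTA + label TSV (via [write_dataset()]), the ground-truth TSV
#' and a YAML echo of the generating spec.
#'
#' @param gen a [generate_dataset()] result.
#' @param spec the [synthetic_spec()] that produced it.
#' @param stem output path stem.
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(gen, spec, stem) {
  paths <- write_dataset(gen$dataset, stem)
  truth <- paste0(stem, "_truth.tsv")
  utils::write.table(gen$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec_path <- paste0(stem, "_spec.yaml")
  yaml::write_yaml(unclass(spec), spec_path)
  invisible(c(paths, truth = truth, spec = spec_path))
}
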