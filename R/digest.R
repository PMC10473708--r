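#' Simulate a peptic peptide map
#'
#' Generates an overlapping peptide map of a protein construct, tunable to the
#' scale of real pepsin digests (mean peptide length and per-residue
#' redundancy). Peptide start positions advance by small seeded steps so the
#' realized redundancy is approximately `target_mean_length /` step, and the
#' final peptide is extended to the C-terminus so sequence coverage is
#' complete.
#'
#' @param sequence One-letter amino-acid string of the construct.
#' @param target_mean_length Desired mean peptide length (residues, >= 4).
#' @param target_redundancy Desired mean per-residue peptide depth (>= 1).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @param spans Optional list of `c(start, end)` pairs that overrides the
#'   random map entirely (seed-free, for hand-countable fixtures).
#' @param protein_id Identifier stored in the `protein` column.
#' @return A tibble of peptide records: `protein`, `start`, `end`,
#'   `sequence`, `max_uptake`.
#' @export
digest <- function(sequence, target_mean_length = 13, target_redundancy = 5.5,
                   seed = 1L, spans = NULL, protein_id = "protein") {
  aa <- check_sequence(sequence)
  L <- length(aa)

  if (is.null(spans)) {
    if (target_mean_length < 4) {
      abort("`target_mean_length` must be >= 4.", class = "hdxdiff_input_error")
    }
    if (target_redundancy < 1) {
      abort("`target_redundancy` must be >= 1.", class = "hdxdiff_input_error")
    }
    if (L < target_mean_length) {
      abort("Sequence shorter than `target_mean_length`.",
            class = "hdxdiff_input_error")
    }
    step <- target_mean_length / target_redundancy
    spans <- withr::with_seed(seed, {
      starts <- 1L
      repeat {
        nxt <- starts[length(starts)] +
          floor(step) + stats::rbinom(1L, 1L, step - floor(step))
        nxt <- max(nxt, starts[length(starts)] + 1L)
        if (nxt + 3L > L) break
        starts <- c(starts, nxt)
      }
      lens <- pmax(4L, round(rnorm(length(starts), target_mean_length,
                                   0.1 * target_mean_length)))
      ends <- pmin(starts + lens - 1L, L)
      # close gaps (each peptide reaches at least the next start) and extend
      # the last peptide to the C-terminus, so coverage is complete
      ends <- pmax(ends, c(starts[-1] - 1L, L))
      ends[length(ends)] <- L
      Map(c, starts, ends)
    })
  }

  starts <- vapply(spans, function(s) as.integer(s[1]), integer(1))
  ends <- vapply(spans, function(s) as.integer(s[2]), integer(1))
  if (any(starts < 1L) || any(ends > L) || any(ends < starts)) {
    abort("Peptide span outside sequence bounds.",
          class = "hdxdiff_coordinate_error")
  }

  seqs <- mapply(function(s, e) paste(aa[s:e], collapse = ""), starts, ends)
  tibble(
    protein = protein_id,
    start = starts,
    end = ends,
    sequence = unname(seqs),
    max_uptake = vapply(seqs, exchangeable_amides, integer(1), USE.NAMES = FALSE)
  )
}

#' Per-residue peptide depth of a map
#'
#' @param peptides Peptide tibble (needs `start`, `end`).
#' @param protein_length Construct length in residues.
#' @return Integer vector of length `protein_length`: the number of peptides
#'   covering each residue.
#' @export
residue_depth <- function(peptides, protein_length) {
  depth <- integer(protein_length)
  for (i in seq_len(nrow(peptides))) {
    idx <- peptides$start[i]:peptides$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}
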