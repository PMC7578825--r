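#' Published group-level summaries for Pearl River black amur bream
#'
#' Small accessor functions for the printed summary tables of the black amur
#' bream (*Megalobrama terminalis*) feeding-ecology study these methods were
#' developed around. They supply realistic default parameterizations for the
#' simulators, desk-reproducible inputs for the overlap and correlation
#' analyses, and the prey-source signatures for the mixing model.
#'
#' * `bream_groupmean_diet()` — group-mean percent-by-weight diet
#'   compositions as one "pseudo-individual" per size group, suitable for
#'   [percent_by_weight()] and [morisita_matrix()].
#' * `bream_prey_sources()` — the twelve prey-source isotope signatures
#'   (mean and SD per tracer) with the study's trophic enrichment factors
#'   (1.3 +/- 0.3 per-mil for d13C, 2.3 +/- 0.18 per-mil for d15N).
#' * `bream_isotope_groups()` — per size group mean, SD and n of muscle
#'   d13C and d15N.
#' * `bream_niche_summary()` — per size group published niche metrics:
#'   WIC/TNW, mean diet similarity, SEA and SEAc.
#'
#' @return A [diet_matrix()], [source_set()], or plain data frame
#'   respectively.
#' @name bream_data
NULL

#' @rdname bream_data
#' @export
bream_groupmean_diet <- function() {
  read_diet_csv(system.file("extdata", "bream_groupmean_pW.csv",
                            package = "trophicniche", mustWork = TRUE))
}

#' @rdname bream_data
#' @export
bream_prey_sources <- function() {
  read_sources_csv(system.file("extdata", "bream_prey_sources.csv",
                               package = "trophicniche", mustWork = TRUE))
}

#' @rdname bream_data
#' @export
bream_isotope_groups <- function() {
  data.frame(
    group = c("small_juvenile", "large_juvenile", "sub_adult", "adult"),
    n = c(11L, 12L, 15L, 8L),
    d13C_mean = c(-24.67, -25.53, -26.10, -25.58),
    d13C_sd = c(1.75, 1.43, 1.52, 1.33),
    d15N_mean = c(11.60, 12.54, 13.53, 14.57),
    d15N_sd = c(2.75, 2.44, 2.69, 3.09),
    stringsAsFactors = FALSE
  )
}

#' @rdname bream_data
#' @export
bream_niche_summary <- function() {
  data.frame(
    group = c("small_juvenile", "large_juvenile", "sub_adult", "adult"),
    n = c(11L, 12L, 15L, 8L),
    wic_over_tnw = c(0.250, 0.951, 0.637, 0.610),
    diet_similarity = c(0.339, 0.185, 0.375, 0.386),
    SEA = c(9.446, 10.041, 11.240, 12.957),
    SEAc = c(10.496, 11.045, 12.104, 15.116),
    stringsAsFactors = FALSE
  )
}
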