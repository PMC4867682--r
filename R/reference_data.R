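# Published treatment-mean tables of the source study, shipped as fixed
# inputs for worked-example consistency checks (per-pot raw data were not
# deposited; only these summary means are available).

#' Packaged reference tables
#'
#' Published treatment means of the emulated study: pot-experiment means
#' (dry matter, tissue P, uptake, fertilizer-derived share, recovery, RAE),
#' incubation means (solution P, dilution parameters m and n, E1min, resin
#' P, fertilizer-derived resin P, microbial P at days 7 and 21), and the
#' seed-P input characterization. Used as fixed inputs by the acceptance
#' checks; they are summary statistics, not raw replicates.
#'
#' @return A list with data frames `pot`, `incubation`, `seed_input`.
#' @export
reference_tables <- function() {
  ext <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "isopart",
                                mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
  }
  list(pot = ext("reference_pot_means.csv"),
       incubation = ext("reference_incubation_means.csv"),
       seed_input = ext("reference_seed_input.csv"))
}
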