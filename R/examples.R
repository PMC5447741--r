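#' Worked example: the published RED-9 to RED-13 refinement accounting
#'
#' Encodes the item accounting of the published refinement as ready-made
#' inputs: the two study candidate pools (15 and 37 retained ids sharing 5
#' overlaps, merging to 47), the domain screen (15 of the 47 fall outside
#' the three RRE domains, leaving 32), and the final candidate audit — the
#' nine tested items with their domains, relative severities and the gaps
#' each covers (the low-range item covers the lowest gap; the
#' loss-of-control item covers the low and middle gaps; the preoccupation
#' item covers the upper-middle gap; the lack-of-satiety item covers the
#' high gap).  Running [select_items()] on this audit with the reference
#' domain tally reproduces the published four-item extension, turning the
#' 9-item base into a 13-item scale.
#'
#' @return List with `study1_ids`, `study2_ids` (candidate pools),
#'   `out_of_domain_ids` (the 15 removed by the domain screen), `audit`
#'   (a `coverage_audit`-shaped data frame over the 9 tested candidates),
#'   `n_gaps`, and `reference_domains` (domains of the 9 base items).
#' @export
refinement_example <- function() {
  shared <- paste0("shared", 1:5)
  study1_ids <- c(shared, paste0("s1_", sprintf("%02d", 1:10)))
  study2_ids <- c(shared, paste0("s2_", sprintf("%02d", 1:32)))
  out_of_domain_ids <- c(paste0("s1_", sprintf("%02d", 1:5)),
                         paste0("s2_", sprintf("%02d", 1:10)))
  # the 9 candidates carried into the final study: domains per the scale's
  # construct assignment, severities ordered low to high, and gap coverage
  # over the five detected gaps (1 = lowest ... 5 = highest)
  audit <- data.frame(
    id = c("debq2", "ei1", "yfas2", "pfs3", "pfs6", "fcqt10", "yfas1",
           "tfeq7", "tfeq39"),
    domain = c("LOSS_OF_CONTROL", "LOSS_OF_CONTROL", "LOSS_OF_CONTROL",
               "LOSS_OF_CONTROL", "LOSS_OF_CONTROL", "PREOCCUPATION",
               "PREOCCUPATION", "LOSS_OF_CONTROL", "LACK_OF_SATIETY"),
    mean_threshold = c(-1.6, -1.3, -0.7, -0.4, -0.2, 0.1, 0.3, 0.5, 1.3),
    stringsAsFactors = FALSE
  )
  audit$gaps_covered <- list(
    debq2 = 1L,            # lowest range
    ei1 = 1L,
    yfas2 = c(2L, 3L),     # low and middle ranges
    pfs3 = 2L,
    pfs6 = 2L,
    fcqt10 = 4L,           # upper-middle range
    yfas1 = 4L,
    tfeq7 = 3L,
    tfeq39 = 5L            # high range
  )
  audit$n_gaps <- lengths(audit$gaps_covered)
  audit$retained <- audit$n_gaps > 0L
  class(audit) <- c("coverage_audit", "data.frame")
  list(study1_ids = study1_ids, study2_ids = study2_ids,
       out_of_domain_ids = out_of_domain_ids, audit = audit, n_gaps = 5L,
       reference_domains = c(rep("LOSS_OF_CONTROL", 4),
                             rep("LACK_OF_SATIETY", 2),
                             rep("PREOCCUPATION", 3)))
}
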