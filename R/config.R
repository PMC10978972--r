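#' Default pipeline configuration
#'
#' One top-level section per module. Values mirror the published procedure
#' where stated (bit floor 100, index floor 30, 95% clustering, >50%
#' replication, E-value ceiling 1e-10 and 100 hits per search for tree
#' building) and this package's documented defaults elsewhere (bootstrap
#' support 0.7, clade purity 1.0, novelty radius 0.04).
#'
#' @return nested configuration list
#' @export
hgt_config <- function() {
  list(
    search = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                  lambda = 0.267, K = 0.041, top_k = 100, max_evalue = 1e-3),
    hgt_index = list(bit_floor = 100, hU_floor = 30, ingroup = "Fungi"),
    cluster = list(threshold = 0.95),
    phylo = list(bootstrap_n = 100, support_min = 0.7, purity = 1.0,
                 max_per_search = 100, max_evalue = 1e-10),
    events = list(min_prevalence = 0.5),
    amplicon = list(min_len = 200, max_len = 380, max_homopolymer = 8,
                    min_identity = 0.96, min_coverage = 0.70,
                    novelty_radius = 0.04),
    cellulosome = list(min_identity = 0.2734, dockerin_domain = "CBM_10")
  )
}

#' Read a pipeline configuration file
#'
#' YAML with one top-level section per module; missing entries fall back to
#' the defaults from [hgt_config()].
#'
#' @param path YAML file
#' @return nested configuration list
#' @export
read_hgt_config <- function(path) {
  override <- yaml::read_yaml(path)
  cfg <- merge_config(hgt_config(), override)
  unknown <- setdiff(names(override), names(hgt_config()))
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
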