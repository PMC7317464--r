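#' Subregional sea-surface-temperature climatology
#'
#' The packaged default environment table: each subregion of the global
#' coral--symbiont network, the ocean-basin region it belongs to, and its
#' mean monthly maximum sea surface temperature for 2005 (`t_mmm_c`, degrees
#' Celsius), the climatological baseline above which bleaching is expected.
#' Host nodes inherit `t_mmm_c` from their subregion.
#'
#' @param include_marginals If `TRUE`, also return the published host-node
#'   and link counts per subregion (`n_hosts`, `n_links`), used by the
#'   synthetic-data generator to size its global-like preset.
#'
#' @return A tibble with columns `subregion`, `region`, `t_mmm_c`, and
#'   optionally `n_hosts`, `n_links`.
#' @export
#' @examples
#' subregion_environment()
subregion_environment <- function(include_marginals = FALSE) {
  env <- tribble(
    ~subregion,           ~region,          ~t_mmm_c, ~n_hosts, ~n_links,
    "Great Barrier Reef", "Pacific Ocean",     28.68,      157,      315,
    "Central Pacific",    "Pacific Ocean",     27.60,       30,      147,
    "Japan",              "Pacific Ocean",     28.54,       58,       84,
    "Eastern Pacific",    "Pacific Ocean",     27.63,       14,       43,
    "Western Pacific",    "Pacific Ocean",     29.56,       16,       24,
    "American Samoa",     "Pacific Ocean",     29.87,        2,       11,
    "Phuket",             "Indian Ocean",      30.38,      140,      404,
    "Western Indian",     "Indian Ocean",      28.97,      109,      272,
    "Western Australia",  "Indian Ocean",      28.78,       20,       55,
    "Western Caribbean",  "Caribbean Sea",     29.72,       52,      122,
    "Eastern Caribbean",  "Caribbean Sea",     29.63,       40,      106,
    "Central Caribbean",  "Caribbean Sea",     29.94,       31,       75,
    "Florida",            "Caribbean Sea",     30.25,       15,       38,
    "Gulf of Mexico",     "Caribbean Sea",     30.54,        1,        1
  )
  if (!include_marginals) env <- select(env, "subregion", "region", "t_mmm_c")
  env
}

# trim + collapse internal whitespace; case preserved (labels are free text)
normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}
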