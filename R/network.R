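#' Read coral--symbiont association records
#'
#' Reads a delimited file of association records into the tibble layout the
#' rest of the package consumes. Required columns are `host_species`,
#' `subregion`, `region`, and `symbiont_type`; `host_family`,
#' `symbiont_genus`, `in_situ`, and `scleractinian` are optional and filled
#' with `"unknown"` / `TRUE` when absent.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param delim Field delimiter; guessed from the file extension by default.
#'
#' @return A tibble of association records.
#' @export
read_associations <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_association_records(raw)
}

#' Coerce a data frame to association records
#'
#' Validates the schema of an association table and normalizes its labels
#' (whitespace trimmed and collapsed; case preserved). Missing optional
#' taxonomy columns become explicit `"unknown"` values.
#'
#' @param records A data frame with at least `host_species`, `subregion`,
#'   `region`, `symbiont_type`.
#' @return A tibble with the full record schema.
#' @export
as_association_records <- function(records) {
  required <- c("host_species", "subregion", "region", "symbiont_type")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("association table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coralnet_schema_error")
  }
  records <- as_tibble(records)
  if (!"host_family" %in% names(records))    records$host_family <- "unknown"
  if (!"symbiont_genus" %in% names(records)) records$symbiont_genus <- "unknown"
  if (!"in_situ" %in% names(records))        records$in_situ <- TRUE
  if (!"scleractinian" %in% names(records))  records$scleractinian <- TRUE
  records |>
    mutate(across(c("host_species", "host_family", "subregion", "region",
                    "symbiont_type", "symbiont_genus"), normalize_label),
           host_family = if_else(.data$host_family == "" | is.na(.data$host_family),
                                 "unknown", .data$host_family),
           symbiont_genus = if_else(.data$symbiont_genus == "" | is.na(.data$symbiont_genus),
                                    "unknown", .data$symbiont_genus),
           in_situ = as.logical(.data$in_situ),
           scleractinian = as.logical(.data$scleractinian)) |>
    select("host_species", "host_family", "subregion", "region",
           "symbiont_type", "symbiont_genus", "in_situ", "scleractinian")
}

#' Filter association records
#'
#' Applies the curation rules used for the global network: keep scleractinian
#' corals, in-situ samples, and records with a known subregion, then drop
#' duplicate associations so that each (host species, subregion, symbiont
#' type) triple appears once. Geographically distinct associations of the
#' same species--symbiont pair are retained. Row order is stable (first
#' occurrence wins).
#'
#' @param records Association records (see [as_association_records()]).
#' @param require_scleractinian,require_in_situ,require_known_subregion
#'   Toggle the individual curation rules.
#' @param known_subregions Character vector of valid subregion labels;
#'   defaults to the packaged environment table.
#'
#' @return The filtered, deduplicated tibble.
#' @export
filter_records <- function(records,
                           require_scleractinian = TRUE,
                           require_in_situ = TRUE,
                           require_known_subregion = TRUE,
                           known_subregions = subregion_environment()$subregion) {
  records <- as_association_records(records)
  if (require_scleractinian) {
    records <- filter(records, !is.na(.data$scleractinian), .data$scleractinian)
  }
  if (require_in_situ) {
    records <- filter(records, !is.na(.data$in_situ), .data$in_situ)
  }
  if (require_known_subregion) {
    records <- filter(records, .data$subregion %in% normalize_label(known_subregions))
  }
  records <- filter(records, .data$host_species != "", .data$symbiont_type != "",
                    .data$subregion != "")
  distinct(records, .data$host_species, .data$subregion, .data$symbiont_type,
           .keep_all = TRUE)
}

host_node_id <- function(species, subregion) paste(species, subregion, sep = " | ")

#' Build a bipartite coral--symbiont network
#'
#' Constructs the bipartite network from filtered association records. Host
#' node identity is the (species, subregion) pair, so a species sampled in
#' several subregions contributes several host nodes, each carrying its
#' subregion's thermal baseline; a Symbiodiniaceae ITS2 type is a single
#' symbiont node regardless of where it was found. One link per unique
#' record.
#'
#' @param records Filtered association records.
#' @param env Environment table mapping `subregion` to `region` and
#'   `t_mmm_c`; defaults to the packaged table.
#'
#' @return A `coral_network`: a list of three tibbles, `hosts` (one row per
#'   host node), `symbionts` (one row per ITS2 type), and `edges`
#'   (host_id, symbiont_id), with deterministic lexicographic node order.
#' @export
#' @examples
#' rec <- tibble::tibble(host_species = "Acropora cervicornis",
#'                       subregion = "Florida", region = "Caribbean Sea",
#'                       symbiont_type = "A3")
#' build_network(rec)
build_network <- function(records, env = subregion_environment()) {
  records <- as_association_records(records)
  env <- mutate(as_tibble(env), subregion = normalize_label(.data$subregion))
  missing_env <- setdiff(unique(records$subregion), env$subregion)
  if (length(missing_env) > 0) {
    abort(paste0("subregion(s) absent from environment table: ",
                 paste(missing_env, collapse = ", ")),
          class = "coralnet_environment_error")
  }
  dup <- records |>
    count(.data$host_species, .data$subregion, .data$symbiont_type) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(paste0(nrow(dup), " duplicate association(s) collapsed to single links"))
    records <- distinct(records, .data$host_species, .data$subregion,
                        .data$symbiont_type, .keep_all = TRUE)
  }

  hosts <- records |>
    distinct(.data$host_species, .data$subregion, .keep_all = TRUE) |>
    transmute(host_id = host_node_id(.data$host_species, .data$subregion),
              species = .data$host_species,
              family = .data$host_family,
              subregion = .data$subregion) |>
    left_join(select(env, "subregion", "region", "t_mmm_c"), by = "subregion") |>
    arrange(.data$host_id)
  symbionts <- records |>
    distinct(.data$symbiont_type, .keep_all = TRUE) |>
    transmute(symbiont_id = .data$symbiont_type,
              genus = .data$symbiont_genus) |>
    arrange(.data$symbiont_id)
  edges <- records |>
    transmute(host_id = host_node_id(.data$host_species, .data$subregion),
              symbiont_id = .data$symbiont_type) |>
    arrange(.data$host_id, .data$symbiont_id)

  new_coral_network(hosts, symbionts, edges)
}

new_coral_network <- function(hosts, symbionts, edges) {
  structure(list(hosts = hosts, symbionts = symbionts, edges = edges),
            class = "coral_network")
}

#' Validate a coral network
#'
#' Checks the structural invariants of a `coral_network`: strict
#' bipartiteness (every edge joins a known host to a known symbiont), no
#' duplicate links, no isolated-by-construction inconsistencies, and an
#' assigned thermal baseline for every host.
#'
#' @param net A `coral_network`.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "coral_network"))
  if (anyDuplicated(net$hosts$host_id))
    abort("duplicate host node ids", class = "coralnet_integrity_error")
  if (anyDuplicated(net$symbionts$symbiont_id))
    abort("duplicate symbiont node ids", class = "coralnet_integrity_error")
  if (!all(net$edges$host_id %in% net$hosts$host_id))
    abort("edge references unknown host node", class = "coralnet_integrity_error")
  if (!all(net$edges$symbiont_id %in% net$symbionts$symbiont_id))
    abort("edge references unknown symbiont node", class = "coralnet_integrity_error")
  if (anyDuplicated(paste(net$edges$host_id, net$edges$symbiont_id, sep = "\r")))
    abort("duplicate links", class = "coralnet_integrity_error")
  if (nrow(net$hosts) > 0 && anyNA(net$hosts$t_mmm_c))
    abort("host node(s) without a T_MMM value", class = "coralnet_integrity_error")
  invisible(net)
}

#' @export
print.coral_network <- function(x, ...) {
  cat("<coral_network>  ", nrow(x$hosts), " hosts + ", nrow(x$symbionts),
      " symbionts, ", nrow(x$edges), " links\n", sep = "")
  if (nrow(x$hosts) > 0) {
    cat("  subregions: ", paste(sort(unique(x$hosts$subregion)), collapse = ", "),
        "\n", sep = "")
  }
  if ("tolerance" %in% names(x$hosts) && !anyNA(x$hosts$tolerance)) {
    cat("  tolerances assigned\n")
  }
  invisible(x)
}

#' Restrict a network to a region or subregion
#'
#' Keeps the host nodes located in `scope` (a region label, a subregion
#' label, or a vector of either), the symbiont nodes retaining at least one
#' link within the scope, and the links between them. An empty result is a
#' valid (empty) network.
#'
#' @param net A `coral_network`.
#' @param scope Region and/or subregion label(s).
#' @return A `coral_network`.
#' @export
subset_network <- function(net, scope) {
  stopifnot(inherits(net, "coral_network"))
  scope <- normalize_label(scope)
  env <- subregion_environment()
  known <- unique(c(env$region, env$subregion, net$hosts$region, net$hosts$subregion))
  unknown <- setdiff(scope, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown scope label(s): ", paste(unknown, collapse = ", ")),
          class = "coralnet_scope_error")
  }
  hosts <- filter(net$hosts, .data$region %in% scope | .data$subregion %in% scope)
  edges <- filter(net$edges, .data$host_id %in% hosts$host_id)
  symbionts <- filter(net$symbionts, .data$symbiont_id %in% edges$symbiont_id)
  out <- new_coral_network(arrange(hosts, .data$host_id),
                           arrange(symbionts, .data$symbiont_id),
                           arrange(edges, .data$host_id, .data$symbiont_id))
  attr(out, "class_model") <- attr(net, "class_model")
  out
}

#' Degree sequence of a network
#'
#' @param net A `coral_network`.
#' @param class `"combined"` (default), `"host"`, or `"symbiont"`.
#' @return A tibble with `node_id`, `class`, `degree` (zero-degree nodes
#'   included).
#' @export
degree_sequence <- function(net, class = c("combined", "host", "symbiont")) {
  class <- match.arg(class)
  hd <- tibble(node_id = net$hosts$host_id, class = "host") |>
    left_join(count(net$edges, .data$host_id, name = "degree"),
              by = c(node_id = "host_id"))
  sy <- tibble(node_id = net$symbionts$symbiont_id, class = "symbiont") |>
    left_join(count(net$edges, .data$symbiont_id, name = "degree"),
              by = c(node_id = "symbiont_id"))
  out <- bind_rows(hd, sy) |>
    mutate(degree = coalesce(.data$degree, 0L))
  if (class != "combined") out <- filter(out, .data$class == .env$class)
  out
}

#' Summarize network structure
#'
#' Node and link counts, mean degree (2L/N), and both connectance variants
#' in circulation for these networks: `connectance_bipartite` =
#' L/(hosts x symbionts), the realized fraction of possible bipartite links,
#' and `connectance_printed` = L/N^2, the convention matching the published
#' per-network values. Neither is used downstream.
#'
#' @param net A `coral_network`.
#' @return A one-row tibble (glance-style).
#' @export
network_summary <- function(net) {
  nh <- nrow(net$hosts); ns <- nrow(net$symbionts); l <- nrow(net$edges)
  n <- nh + ns
  tibble(
    n_nodes = n, n_hosts = nh, n_symbionts = ns,
    n_species = length(unique(net$hosts$species)),
    n_links = l,
    mean_degree = if (n > 0) 2 * l / n else NA_real_,
    connectance_bipartite = if (nh > 0 && ns > 0) l / (nh * ns) else NA_real_,
    connectance_printed = if (n > 0) l / n^2 else NA_real_
  )
}

#' @export
glance.coral_network <- function(x, ...) network_summary(x)

#' Export the edge list of a network
#'
#' @param net A `coral_network`.
#' @return A tibble with one row per link carrying the full record schema,
#'   suitable for [build_network()] round-trips and for writing with
#'   [readr::write_csv()].
#' @export
edges_table <- function(net) {
  net$edges |>
    left_join(net$hosts, by = "host_id") |>
    left_join(net$symbionts, by = "symbiont_id") |>
    transmute(host_species = .data$species, host_family = .data$family,
              subregion = .data$subregion, region = .data$region,
              symbiont_type = .data$symbiont_id, symbiont_genus = .data$genus,
              in_situ = TRUE, scleractinian = TRUE)
}

#' Convert to an igraph bipartite graph
#'
#' @param net A `coral_network`.
#' @return An [igraph::graph] with vertex attributes `type` (`FALSE` hosts,
#'   `TRUE` symbionts), `subregion`, `t_mmm_c`, and `tolerance` where
#'   assigned.
#' @export
as_igraph <- function(net) {
  verts <- bind_rows(
    tibble(name = net$hosts$host_id, type = FALSE,
           subregion = net$hosts$subregion, t_mmm_c = net$hosts$t_mmm_c,
           tolerance = net$hosts$tolerance %||% NA_real_),
    tibble(name = net$symbionts$symbiont_id, type = TRUE,
           subregion = NA_character_, t_mmm_c = NA_real_,
           tolerance = net$symbionts$tolerance %||% NA_real_)
  )
  igraph::graph_from_data_frame(
    d = tibble(from = net$edges$host_id, to = net$edges$symbiont_id),
    directed = FALSE, vertices = verts)
}

#' Write a network to disk
#'
#' Writes the edge list as CSV and, optionally, the graph as GraphML.
#'
#' @param net A `coral_network`.
#' @param edges_path Path for the edge-list CSV.
#' @param graphml_path Optional path for a GraphML export.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path, graphml_path = NULL) {
  readr::write_csv(edges_table(net), edges_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(net)
}
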