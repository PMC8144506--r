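#' Pipeline orchestration
#'
#' `run_pipeline()` executes the four analysis stages in order --
#' expression filtering/transform, shared-miRNA candidate enumeration,
#' PC-stable + local-IDA effect estimation, correlation-based edge calling
#' with hub selection -- writes every intermediate table plus a JSON run
#' manifest, and is deterministic: identical configuration and inputs
#' yield byte-identical tables.
#'
#' @name pipeline
#' @keywords internal
NULL

.CONFIG_DEFAULTS <- list(
  expression = NA_character_,
  annotation = NA_character_,
  evidence_lncrna = NA_character_,
  evidence_mrna = NA_character_,
  out_dir = NA_character_,
  min_total = 100,
  transform = "log2p1",
  min_shared = 1L,
  sharing_q_max = 0.05,
  alpha = 0.01,
  max_cond_size = 3L,
  edge_q_max = 0.05,
  effect_min = -Inf,
  require_positive_r = TRUE,
  hub_fraction = 0.2,
  seed = 1L
)

.coerce_config_value <- function(key, value) {
  tmpl <- .CONFIG_DEFAULTS[[key]]
  if (is.character(tmpl)) return(as.character(value))
  if (is.logical(tmpl)) {
    v <- tolower(trimws(value))
    if (!v %in% c("true", "false", "yes", "no", "1", "0")) {
      stop("config key '", key, "' expects a logical, got '", value, "'")
    }
    return(v %in% c("true", "yes", "1"))
  }
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) stop("config key '", key, "' expects a number, got '", value, "'")
  if (is.integer(tmpl)) {
    if (is.finite(v) && v != floor(v)) stop("config key '", key, "' expects an integer")
    if (is.finite(v)) v <- as.integer(v)
  }
  v
}

.check_config_ranges <- function(cfg) {
  chk <- function(ok, key, domain) {
    if (!ok) stop("config key '", key, "' out of range; accepted domain: ", domain)
  }
  chk(cfg$min_total >= 0, "min_total", ">= 0")
  chk(cfg$transform %in% c("log2p1", "none"), "transform", "log2p1 | none")
  chk(cfg$min_shared >= 1, "min_shared", ">= 1")
  chk(cfg$sharing_q_max > 0 && cfg$sharing_q_max <= 1, "sharing_q_max", "(0, 1]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "(0, 1)")
  chk(is.infinite(cfg$max_cond_size) || cfg$max_cond_size >= 0, "max_cond_size", ">= 0 or Inf")
  chk(cfg$edge_q_max > 0 && cfg$edge_q_max <= 1, "edge_q_max", "(0, 1]")
  chk(cfg$hub_fraction > 0 && cfg$hub_fraction <= 1, "hub_fraction", "(0, 1]")
  invisible(cfg)
}

#' Read and validate a pipeline configuration
#'
#' Flat key-value plain text (`key = value`, `#` comments). Missing keys
#' take their documented defaults; unknown keys and out-of-range values
#' are rejected with the offending key named.
#'
#' @param path path to a configuration file, or a named list of overrides
#'   (useful programmatically).
#' @return A `pipeline_config` list of effective settings.
#' @export
validate_config <- function(path) {
  overrides <- list()
  if (is.list(path)) {
    overrides <- path
    unknown <- setdiff(names(overrides), names(.CONFIG_DEFAULTS))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) stop("malformed config line (expected key = value): '", ln, "'")
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      if (!key %in% names(.CONFIG_DEFAULTS)) {
        stop("unknown config key: '", key, "'")
      }
      overrides[[key]] <- .coerce_config_value(key, val)
    }
  }
  cfg <- .CONFIG_DEFAULTS
  for (key in names(overrides)) cfg[[key]] <- overrides[[key]]
  .check_config_ranges(cfg)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the sponge-network pipeline
#'
#' Executes filter -> transform -> candidate enumeration -> causal
#' effects -> edge calling -> hub selection, writing `candidates.tsv`,
#' `effects.tsv`, `edges.tsv`, `hubs.tsv`, `network.graphml`,
#' `cpdag.graphml` and `manifest.json` into the output directory. All
#' tables are written only after every stage has succeeded, so a failing
#' run leaves no partial outputs; the error names the failing stage.
#'
#' @param config a `pipeline_config`, a config file path, or a named list
#'   of overrides (see [validate_config()]).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return Invisible list with the in-memory stage results
#'   (`candidates`, `effects`, `network`, `hubs`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.na(cfg$out_dir)) stop("no output directory configured")
  for (key in c("expression", "annotation", "evidence_lncrna", "evidence_mrna")) {
    if (is.na(cfg[[key]])) stop("config key '", key, "' is required")
    if (!file.exists(cfg[[key]])) stop("input not found for '", key, "': ", cfg[[key]])
  }

  counts <- list()
  expr <- .stage("expression", {
    x <- read_expression(cfg$expression)
    counts$genes_loaded <- nrow(x)
    x <- filter_low_expression(x, cfg$min_total)
    counts$genes_kept <- nrow(x)
    transform_expression(x, cfg$transform)
  })
  anno <- .stage("expression", read_annotation(cfg$annotation))
  split <- .stage("expression", split_by_biotype(expr, anno))
  counts$lncrnas_expressed <- nrow(split$lncrna)
  counts$mrnas_expressed <- nrow(split$mrna)

  evidence <- .stage("interactions", {
    merge_interactions(load_interactions(cfg$evidence_lncrna, "lncRNA"),
                       load_interactions(cfg$evidence_mrna, "mRNA"))
  })
  counts$evidence_records <- n_interactions(evidence)
  counts$mirna_universe <- length(mirna_universe(evidence))

  candidates <- .stage("sharing", {
    rec <- evidence$records
    lnc_ids <- intersect(rownames(split$lncrna),
                         rec$target_id[rec$target_class == "lncRNA"])
    mrna_ids <- intersect(rownames(split$mrna),
                          rec$target_id[rec$target_class == "mRNA"])
    counts$lncrnas_with_evidence <- length(lnc_ids)
    counts$mrnas_with_evidence <- length(mrna_ids)
    message("sharing: ", nrow(split$lncrna) - length(lnc_ids), " lncRNAs and ",
            nrow(split$mrna) - length(mrna_ids),
            " mRNAs lack interaction evidence and were excluded")
    all_pairs <- enumerate_candidates(evidence, lnc_ids, mrna_ids, cfg$min_shared)
    counts$candidates_enumerated <- nrow(all_pairs)
    filter_candidates(all_pairs, cfg$sharing_q_max)
  })
  counts$candidates_significant <- nrow(candidates)

  effects <- .stage("causal", {
    estimate_pair_effects(expr, candidates,
                          ci_cfg(cfg$alpha, cfg$max_cond_size))
  })

  net <- .stage("network", {
    call_edges(expr, candidates, effects, q_max = cfg$edge_q_max,
               effect_min = cfg$effect_min,
               require_positive_r = cfg$require_positive_r)
  })
  counts$edges_called <- nrow(net$edges)

  hubs <- if (nrow(net$edges)) {
    .stage("hubs", select_hubs(net, cfg$hub_fraction))
  } else NULL
  counts$hub_lncrnas <- if (is.null(hubs)) 0L else length(hubs$hubs)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    candidates = file.path(cfg$out_dir, "candidates.tsv"),
    effects = file.path(cfg$out_dir, "effects.tsv"),
    edges = file.path(cfg$out_dir, "edges.tsv"),
    hubs = file.path(cfg$out_dir, "hubs.tsv"),
    network_graphml = file.path(cfg$out_dir, "network.graphml"),
    cpdag_graphml = file.path(cfg$out_dir, "cpdag.graphml"),
    manifest = file.path(cfg$out_dir, "manifest.json"))
  .stage("write", {
    write_candidates(candidates, paths$candidates)
    write_effects(effects, paths$effects)
    write_edges(net, paths$edges)
    if (is.null(hubs)) {
      writeLines("lnc_id\tdegree", paths$hubs)
    } else {
      write_hubs(hubs, paths$hubs)
    }
    write_network_graphml(net, paths$network_graphml)
    g <- attr(effects, "cpdag")
    if (!is.null(g)) write_cpdag_graphml(g, paths$cpdag_graphml)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("spongenet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(unlist(cfg[c(
      "expression", "annotation", "evidence_lncrna", "evidence_mrna")]))),
    counts = counts)
  # -Inf is not representable in JSON; serialize as string
  manifest$config$effect_min <- as.character(manifest$config$effect_min)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  for (nm in names(counts)) message("pipeline: ", nm, " = ", counts[[nm]])
  invisible(list(candidates = candidates, effects = effects, network = net,
                 hubs = hubs, manifest = manifest, paths = paths))
}
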