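# End-to-end orchestration with plain-file stage handoff. Each stage reads
# its inputs from disk, writes its outputs and a manifest of input/output
# file hashes; a rerun with identical config and seed is byte-identical.

#' Run the accounting pipeline
#'
#' Executes the enabled stages in order: `generate` (synthetic world),
#' `footprint` (hybrid MRIO consumption footprints), `allocate` (spatial
#' allocation), `loss` (species-loss account), `flows` (embodied trade),
#' `attribute` (final-product attribution) and `ctv` (country decomposition
#' and contribution-to-variance). Stages communicate exclusively through
#' files under `out_dir`, so any stage can be rerun from the caches of its
#' predecessors; a disabled stage whose cache is missing is a dependency
#' error.
#'
#' @param config a [world_config()], a plain list of its arguments, or the
#'   path of a YAML file holding them.
#' @param out_dir output directory.
#' @param stages character vector of stages to run.
#' @param grouping optional named character vector mapping regions to report
#'   groups for the flow matrix.
#' @param strict error (rather than record) when a conservation check
#'   fails.
#' @param tol relative tolerance for conservation checks.
#' @return An object of class `pipeline_report`: per-stage manifests,
#'   conservation results and headline outputs.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("generate", "footprint", "allocate",
                                    "loss", "flows", "attribute", "ctv"),
                         grouping = NULL, strict = TRUE, tol = 1e-9) {
  all_stages <- c("generate", "footprint", "allocate", "loss", "flows",
                  "attribute", "ctv")
  if (!all(stages %in% all_stages))
    abort_config(paste0("run_pipeline(): unknown stage(s): ",
                        paste(setdiff(stages, all_stages), collapse = ", ")))
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "world_config"))
    config <- do.call(world_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(world = file.path(out_dir, "world"),
                footprint = file.path(out_dir, "footprint"),
                allocated = file.path(out_dir, "allocated"),
                loss = file.path(out_dir, "loss"),
                report = file.path(out_dir, "report"))
  dir.create(paths$report, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  conservation <- list()
  note <- function(name, res) {
    conservation[[name]] <<- res
    if (strict && !res$pass)
      abort_validation(sprintf("run_pipeline(): conservation check '%s' failed (max rel diff %.3e)",
                               name, res$max_rel_diff))
  }
  manifest <- function(stage, inputs, outputs) {
    rel_md5 <- function(files) {
      files <- sort(files)
      h <- tools::md5sum(files)
      # keys relative to out_dir so reruns in different locations compare
      stats::setNames(as.list(unname(h)),
                      sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                           normalizePath(out_dir)), "/?"),
                          "", normalizePath(files)))
    }
    m <- list(stage = stage,
              inputs = rel_md5(inputs),
              outputs = rel_md5(outputs))
    jsonlite::write_json(m, file.path(out_dir, paste0("manifest_", stage,
                                                      ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
    manifests[[stage]] <<- m
  }
  files_of <- function(dir) list.files(dir, full.names = TRUE,
                                       recursive = TRUE)

  if ("generate" %in% stages) {
    world <- generate_world(config)
    write_world(world, paths$world)
    manifest("generate", character(0), files_of(paths$world))
  }
  world <- read_world(paths$world)

  if ("footprint" %in% stages) {
    economy <- world_economy(world)
    fp <- consumption_footprint(economy, world$extension, world$phys$y,
                                world$mon$y)
    write_footprint(fp, paths$footprint)
    cons <- footprint_conservation(fp, tol)
    utils::write.csv(data.frame(check = "footprint_conservation",
                                max_rel_diff = cons$max_rel_diff,
                                pass = cons$pass),
                     file.path(paths$report, "footprint_conservation.csv"),
                     row.names = FALSE)
    note("footprint_conservation", cons)
    manifest("footprint", files_of(paths$world), files_of(paths$footprint))
  }

  need <- function(stage) any(stages %in% stage)
  if (need(c("allocate", "loss", "flows", "attribute", "ctv")))
    footprint <- read_footprint(paths$footprint, world)

  if ("allocate" %in% stages) {
    shares <- normalize_distribution(world$grid, world$extension)
    grid <- allocate_land(footprint, shares, world$masks)
    write_allocated(grid, paths$allocated)
    cons <- allocation_conservation(grid, footprint, world$masks, tol)
    utils::write.csv(data.frame(check = "allocation_conservation",
                                max_rel_diff = cons$max_rel_diff,
                                pass = cons$pass),
                     file.path(paths$report, "allocation_conservation.csv"),
                     row.names = FALSE)
    note("allocation_conservation", cons)
    manifest("allocate", c(files_of(paths$world), files_of(paths$footprint)),
             files_of(paths$allocated))
  }

  if ("loss" %in% stages) {
    grid <- read_allocated(paths$allocated, world)
    shares <- normalize_distribution(world$grid, world$extension)
    account <- species_loss(grid, world$cfs, world$masks,
                            footprint = footprint, shares = shares)
    write_account(account, paths$loss)
    rel <- relative_loss(account)
    utils::write.csv(data.frame(taxon = names(rel),
                                share_of_global_richness = as.numeric(rel)),
                     file.path(paths$report, "relative_loss.csv"),
                     row.names = FALSE)
    manifest("loss", c(files_of(paths$world), files_of(paths$allocated)),
             files_of(paths$loss))
  }

  results <- list()
  if (need(c("flows", "attribute", "ctv")))
    account <- read_account(paths$loss, world)

  if ("flows" %in% stages) {
    fl <- trade_flows(account, grouping)
    flows_df <- array_to_df(fl$flows, value = "species_lost")
    utils::write.csv(flows_df, file.path(paths$report, "flows.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(taxon = names(fl$trade_share),
                                trade_share_pct = 100 * as.numeric(fl$trade_share)),
                     file.path(paths$report, "trade_share.csv"),
                     row.names = FALSE)
    results$flows <- fl
    manifest("flows", files_of(paths$loss),
             file.path(paths$report, c("flows.csv", "trade_share.csv")))
  }

  if ("attribute" %in% stages) {
    at <- product_attribution(account)
    utils::write.csv(at$table, file.path(paths$report, "attribution.csv"),
                     row.names = FALSE)
    results$attribution <- at
    manifest("attribute", files_of(paths$loss),
             file.path(paths$report, "attribution.csv"))
  }

  if ("ctv" %in% stages) {
    grid <- read_allocated(paths$allocated, world)
    dec <- decompose_kba_loss(account, grid, world$masks, world$cfs)
    ctv_res <- ctv(dec)
    utils::write.csv(cbind(factor = rownames(ctv_res$ctv),
                           as.data.frame(ctv_res$ctv)),
                     file.path(paths$report, "ctv.csv"), row.names = FALSE)
    dec_df <- data.frame(region = dec$regions, kba_area_m2 = dec$kba_area,
                         land_use_m2 = dec$land_use)
    utils::write.csv(dec_df, file.path(paths$report, "decomposition.csv"),
                     row.names = FALSE)
    results$ctv <- ctv_res
    results$decomposition <- dec
    manifest("ctv", c(files_of(paths$loss), files_of(paths$allocated)),
             file.path(paths$report, c("ctv.csv", "decomposition.csv")))
  }

  structure(list(manifests = manifests, conservation = conservation,
                 results = results, paths = paths, out_dir = out_dir,
                 pass = all(vapply(conservation, `[[`, logical(1), "pass"))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages run: ",
      paste(names(x$manifests), collapse = ", "), "\n", sep = "")
  for (nm in names(x$conservation))
    cat(sprintf("  %-26s %s (max rel diff %.3e)\n", nm,
                ifelse(x$conservation[[nm]]$pass, "ok", "FAIL"),
                x$conservation[[nm]]$max_rel_diff))
  invisible(x)
}

#' Hash all pipeline outputs
#'
#' MD5 of every file under an output directory (sorted relative paths),
#' used to verify byte-identical reruns.
#'
#' @param out_dir pipeline output directory.
#' @return Named character vector of MD5 hashes keyed by relative path.
#' @export
pipeline_hashes <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  h <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(unname(h), files)
}
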