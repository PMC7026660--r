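#' Run the full comparative chromatin-dynamics analysis
#'
#' Orchestrates simulate -> fit -> compare -> tree -> screen from one
#' declarative config (a YAML file or an equivalent nested list) and
#' writes all stage outputs plus a checksum manifest to the output
#' directory. Reruns with the same config and seed are byte-identical.
#'
#' Config keys (defaults in parentheses): `out_dir`; `seed` (1);
#' `n_modes` (500, clamped to the available spectrum); `window_factor`
#' (4); `hm_fraction` (0.10); `aggregate` ("max"); `reference` (first
#' cell); `synthetic`: `n_loci`, `bin_size` (50000), `n_chromosomes`
#' (1), `tad_boundaries`, `decay_exponent` (1), `intra_tad_boost` (3),
#' `noise_level` (0.1), `strength` (0.2), `cells` (list of `label`,
#' `permutation`, `hm_loci`); `screen`: `contamination` (0.2),
#' `n_decoy_sets` (30), `genes_per_bin` (1). Alternatively `inputs`:
#' a named list of triplet/bin-table path pairs replaces the simulate
#' stage.
#'
#' @param config path to a YAML config or a nested list.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out <- cfg$out_dir
  if (is.null(out)) stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  n_modes <- if (is.null(cfg$n_modes)) 500L else as.integer(cfg$n_modes)
  wf <- if (is.null(cfg$window_factor)) 4 else cfg$window_factor
  hm_frac <- if (is.null(cfg$hm_fraction)) 0.10 else cfg$hm_fraction
  aggregate <- if (is.null(cfg$aggregate)) "max" else cfg$aggregate
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S"),
                                   " [chromodyn] ", ...)
  files <- character()
  emit <- function(x, name, ...) {
    p <- file.path(out, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, ...)
    files <<- c(files, p)
    p
  }

  ## ---- stage: simulate or load -------------------------------------
  if (!is.null(cfg$inputs)) {
    log_msg("loading ", length(cfg$inputs), " contact maps")
    maps <- lapply(cfg$inputs, function(x)
      read_contact_map(x$matrix, format = "triplet",
                       bins_path = x$bins,
                       bin_size = if (is.null(x$bin_size)) 50000L
                                  else x$bin_size))
    truth <- NULL
  } else {
    sy <- cfg$synthetic
    if (is.null(sy)) stop("config needs either inputs or synthetic")
    log_msg("simulating base map (", sy$n_loci, " loci)")
    spec <- synth_spec(
      n_loci = sy$n_loci,
      bin_size = if (is.null(sy$bin_size)) 50000L else sy$bin_size,
      n_chromosomes = if (is.null(sy$n_chromosomes)) 1L else sy$n_chromosomes,
      tad_boundaries = if (is.null(sy$tad_boundaries)) integer()
                       else sy$tad_boundaries,
      decay_exponent = if (is.null(sy$decay_exponent)) 1 else sy$decay_exponent,
      intra_tad_boost = if (is.null(sy$intra_tad_boost)) 3
                        else sy$intra_tad_boost,
      noise_level = if (is.null(sy$noise_level)) 0.1 else sy$noise_level,
      seed = seed)
    base <- filter_bins(generate_contact_map(spec))
    perts <- lapply(sy$cells, function(cc)
      planted_perturbation(
        mode_permutation = if (is.null(cc$permutation)) integer()
                           else as.integer(cc$permutation),
        hm_loci = if (is.null(cc$hm_loci)) integer()
                  else as.integer(cc$hm_loci),
        cell_label = cc$label))
    maps <- generate_cell_family(
      base, perts,
      strength = if (is.null(sy$strength)) 0.2 else sy$strength,
      seed = seed + 1L)
    truth <- perts
    for (lab in names(maps))
      write_contact_map(maps[[lab]],
                        emit_path <- file.path(out, paste0("map_", lab, ".tsv")),
                        file.path(out, paste0("bins_", lab, ".tsv")))
    files <- c(files, file.path(out, paste0("map_", names(maps), ".tsv")),
               file.path(out, paste0("bins_", names(maps), ".tsv")))
  }
  labels <- names(maps)

  ## ---- stage: gnm ---------------------------------------------------
  n_avail <- nrow(maps[[1L]]$matrix) - 1L
  if (n_modes > n_avail) {
    log_msg("warning: n_modes = ", n_modes, " clamped to ", n_avail)
    n_modes <- n_avail
  }
  log_msg("fitting GNMs (", n_modes, " modes x ", length(maps), " cells)")
  fits <- lapply(labels, function(l)
    gnm(maps[[l]], n_modes = n_modes, label = l))
  names(fits) <- labels
  profiles <- lapply(fits, fluctuations, normalized = TRUE)
  prof_tab <- data.frame(bin = seq_len(fits[[1L]]$n) - 1L,
                         vapply(profiles, as.numeric,
                                numeric(fits[[1L]]$n)))
  emit(prof_tab, "mobility_profiles.tsv", row.names = FALSE)

  ## ---- stage: compare ----------------------------------------------
  ref <- if (is.null(cfg$reference)) labels[[1L]] else cfg$reference
  log_msg("mode matching against reference ", ref)
  m_match <- min(n_modes, max(10L, n_modes %/% 4L))
  matchings <- lapply(labels, function(l) {
    if (l == ref) return(NULL)
    match_modes(fits[[ref]], fits[[l]], m = m_match, window_factor = wf)
  })
  names(matchings) <- labels
  for (l in setdiff(labels, ref)) {
    mm <- matchings[[l]]
    emit(data.frame(ref_mode = seq_len(mm$m),
                    cand_mode = mm$assignment,
                    overlap = mm$overlaps),
         paste0("matching_", ref, "_vs_", l, ".tsv"), row.names = FALSE)
  }
  S_ref <- mode_overlap(fits[[ref]], fits[[setdiff(labels, ref)[1L]]],
                        m_a = min(10L, n_modes), m_b = min(10L, n_modes))
  emit(round(unclass(S_ref), 6), "overlap_ref_pair.tsv",
       row.names = FALSE, col.names = FALSE)
  cons_before <- conservation_profile(fits, m = m_match)
  cons_after <- conservation_profile(fits, m = m_match,
                                     matchings = matchings)
  emit(data.frame(mode = seq_len(m_match), before = cons_before,
                  after = cons_after),
       "conservation_profile.tsv", row.names = FALSE)

  matched_profiles <- lapply(labels, function(l) {
    if (l == ref) profiles[[l]]
    else normalize_profile(matched_mobility(fits[[l]], matchings[[l]]))
  })
  names(matched_profiles) <- labels
  pair_r <- function(pp) {
    r <- diag(1, length(labels)); dimnames(r) <- list(labels, labels)
    for (i in seq_along(labels)[-1L]) for (j in seq_len(i - 1L))
      r[i, j] <- r[j, i] <- profile_correlation(pp[[i]], pp[[j]])
    r
  }
  emit(round(pair_r(profiles), 6), "profile_correlation_before.tsv")
  emit(round(pair_r(matched_profiles), 6), "profile_correlation_after.tsv")

  ## ---- stage: tree --------------------------------------------------
  log_msg("covariance overlaps and cell trees")
  per_chrom <- lapply(unique(fits[[1L]]$bins$chrom), function(ch) {
    D <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    cfits <- lapply(labels, function(l) {
      on_ch <- maps[[l]]$bins$chrom == ch
      sub <- contact_map(maps[[l]]$matrix[on_ch, on_ch, drop = FALSE],
                         bins = maps[[l]]$bins[on_ch, , drop = FALSE],
                         bin_size = maps[[l]]$bin_size, provenance = l)
      gnm(sub, n_modes = min(n_modes, sum(on_ch) - 1L), label = l)
    })
    names(cfits) <- labels
    for (i in seq_along(labels)[-1L]) for (j in seq_len(i - 1L)) {
      ab <- align_fits(cfits[[i]], cfits[[j]])
      L <- covariance_overlap(ab[[1L]], ab[[2L]])
      D[i, j] <- D[j, i] <- covariance_distance(L)
    }
    D
  })
  names(per_chrom) <- unique(fits[[1L]]$bins$chrom)
  graph <- build_distance_graph(per_chrom, aggregate = aggregate)
  emit(round(unclass(graph), 6), "distance_graph.tsv")
  mst <- minimum_spanning_tree(graph)
  write_newick(mst, file.path(out, "tree_mst.nwk"))
  files <- c(files, file.path(out, "tree_mst.nwk"))
  if (length(labels) >= 3) {
    njt <- neighbor_joining(graph)
    write_newick(njt, file.path(out, "tree_nj.nwk"))
    files <- c(files, file.path(out, "tree_nj.nwk"))
  }

  ## ---- stage: hmg screen ---------------------------------------------
  log_msg("highly-mobile-gene screening")
  sc <- if (is.null(cfg$screen)) list() else cfg$screen
  rel <- relative_mobility(profiles)
  bins <- fits[[1L]]$bins
  ann <- generate_gene_annotation(
    n_loci = nrow(bins), bin_size = maps[[1L]]$bin_size,
    genes_per_bin = if (is.null(sc$genes_per_bin)) 1L
                    else sc$genes_per_bin,
    seed = seed + 2L, bins = bins)
  write_bed(ann, file.path(out, "genes.bed"))
  files <- c(files, file.path(out, "genes.bed"))
  hmg <- lapply(labels, function(l)
    loci_to_genes(call_hm_loci(rel[[l]], fraction = hm_frac), ann, bins))
  names(hmg) <- labels
  heg <- generate_heg_collection(
    hmg, universe = ann$gene,
    n_decoy_sets = if (is.null(sc$n_decoy_sets)) 30L else sc$n_decoy_sets,
    contamination = if (is.null(sc$contamination)) 0.2
                    else sc$contamination,
    seed = seed + 3L)
  write_gmt(heg, file.path(out, "heg_collection.gmt"))
  files <- c(files, file.path(out, "heg_collection.gmt"))
  screening <- do.call(rbind, lapply(labels, function(l) {
    res <- screen(hmg[[l]], heg, query_label = l)
    cbind(query = l, res$ranking, self_rank = res$self_rank)
  }))
  emit(screening, "screening.tsv", row.names = FALSE)

  ## ---- manifest ------------------------------------------------------
  files <- unique(files)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("done: ", nrow(manifest), " files in ", out)
  invisible(manifest)
}
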