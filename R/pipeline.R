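#' Read and validate a pipeline configuration file
#'
#' The configuration is a single human-editable YAML file; see the package
#' vignette for the full key reference. Referenced input paths are checked
#' at validation time and thresholds must lie in their documented ranges.
#'
#' @param path YAML file.
#' @param base_dir Directory relative paths are resolved against (default:
#'   the config file's directory).
#' @return Named list of validated configuration values.
#' @export
read_pipeline_config <- function(path, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base_dir, p)))
      p <- file.path(base_dir, p)
    p
  }
  for (k in c("alignment", "tree")) cfg[[k]] <- resolve(cfg[[k]])
  if (!is.null(cfg$structures))
    cfg$structures <- lapply(cfg$structures, function(s) {
      s$path <- resolve(s$path); s
    })
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  for (k in c("alignment", "tree"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured ", k, " file does not exist: ", cfg[[k]])
  if (!is.null(cfg$structures))
    for (s in cfg$structures)
      if (!file.exists(s$path))
        stop("configured structure file does not exist: ", s$path)
  th <- cfg$altall_threshold
  if (!is.null(th) && (th <= 0 || th >= 1))
    stop("altall_threshold must be in (0, 1)")
  if (!is.null(cfg$max_exceptions) && cfg$max_exceptions < 0)
    stop("max_exceptions must be >= 0")
  cfg
}

manifest_entry <- function(cfg, inputs, seed) {
  list(package = "paleoprot",
       version = as.character(utils::packageVersion("paleoprot")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config = cfg,
       input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
}

#' Run the evolutionary stage of the pipeline
#'
#' Fits the substitution model's free rate parameters by maximum
#' likelihood, reconstructs the two configured ancestors (ML and AltAll
#' sequences, posterior tables, summaries), enumerates the amino-acid
#' replacements on the branch between them, applies the
#' descendant-conservation filter, maps sites to the reference numbering,
#' and computes pairwise identities under all three denominator
#' conventions. All outputs plus a machine-readable run manifest are
#' written under `config$out_dir`.
#'
#' Required config keys: `alignment`, `tree`, `out_dir`, `ancestor_a` and
#' `ancestor_b` (each a list with `name` and `leaves`), `descendants`
#' (leaf names of the focal clade's extant members). Optional:
#' `reference_taxon`, `reference_offset` (default 1), `model` (list:
#' `frequencies` "observed"/"model", `alpha`, `k`, `p_inv`, `free`),
#' `altall_threshold` (default 0.25), `max_exceptions` (default 1),
#' `seed` (default 1).
#'
#' @param config A validated configuration list ([read_pipeline_config()]).
#' @return Report list with the fitted model, both reconstructions, the
#'   conservation report, identity table and file paths, invisibly usable
#'   downstream.
#' @export
run_evolution_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  for (k in c("alignment", "tree", "out_dir", "ancestor_a", "ancestor_b"))
    if (is.null(cfg[[k]])) stop("config key missing: ", k)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- read_alignment(cfg$alignment)
  tree <- read_tree(cfg$tree)
  for (anc in list(cfg$ancestor_a, cfg$ancestor_b)) {
    absent <- setdiff(anc$leaves, tree$tip.label)
    if (length(absent))
      stop("ancestor '", anc$name, "' clade leaves not in tree: ",
           paste(absent, collapse = ", "))
  }

  mcfg <- cfg$model
  model <- build_substitution_model(
    exchangeabilities = mcfg$exchangeabilities %||% "JTT",
    frequencies = mcfg$frequencies %||% "observed",
    alignment = aln)
  rates0 <- site_rate_model(mcfg$alpha %||% 1, mcfg$k %||% 4L,
                            mcfg$p_inv %||% 0)
  free <- mcfg$free %||% c("alpha", "p_inv")
  fit <- if (length(free)) {
    optimize_parameters(tree, aln, model, rates0, free = unlist(free))
  } else {
    list(model = model, rates = rates0, tree = tree,
         loglik = total_log_likelihood(tree, aln, model, rates0),
         converged = NA, iterations = 0L)
  }

  th <- cfg$altall_threshold %||% 0.25
  recs <- list()
  for (anc in list(cfg$ancestor_a, cfg$ancestor_b)) {
    rec <- marginal_posteriors(fit$tree, aln, fit$model, fit$rates,
                               node = anc$leaves, altall_threshold = th)
    write_reconstruction(rec, cfg$out_dir, anc$name)
    recs[[anc$name]] <- rec
  }
  name_a <- cfg$ancestor_a$name; name_b <- cfg$ancestor_b$name

  numbering <- NULL
  if (!is.null(cfg$reference_taxon))
    numbering <- map_reference_numbering(aln, cfg$reference_taxon,
                                         cfg$reference_offset %||% 1L)
  subs <- enumerate_substitutions(ml_sequence(recs[[name_a]]),
                                  ml_sequence(recs[[name_b]]), numbering)
  report <- subs
  if (!is.null(cfg$descendants)) {
    absent <- setdiff(unlist(cfg$descendants), aln$names)
    if (length(absent))
      stop("descendant sequences not in alignment: ",
           paste(absent, collapse = ", "))
    desc <- alignment_from_matrix(
      aln$matrix[unlist(cfg$descendants), , drop = FALSE])
    report <- conservation_filter(subs, desc, cfg$max_exceptions %||% 1L)
  }
  f_events <- file.path(cfg$out_dir, "substitution_events.tsv")
  write_events_tsv(report, f_events)

  identity <- list()
  cmp <- list(c(name_a, name_b))
  if (!is.null(cfg$reference_taxon))
    cmp <- c(cmp, list(c(name_a, cfg$reference_taxon)))
  seq_of <- function(nm) {
    if (nm %in% names(recs)) ml_sequence(recs[[nm]])
    else paste(aln$matrix[nm, ], collapse = "")
  }
  for (pair in cmp) {
    for (conv in c("both-ungapped", "either-ungapped", "alignment-length")) {
      id <- pairwise_identity(seq_of(pair[1L]), seq_of(pair[2L]), conv)
      identity[[paste(pair[1L], pair[2L], conv, sep = "|")]] <-
        c(list(a = pair[1L], b = pair[2L]), id)
    }
  }
  f_ident <- file.path(cfg$out_dir, "identity_report.json")
  jsonlite::write_json(identity, f_ident, auto_unbox = TRUE, digits = NA)

  manifest <- manifest_entry(cfg, c(cfg$alignment, cfg$tree),
                             cfg$seed %||% 1L)
  manifest$loglik <- fit$loglik
  manifest$fitted <- list(alpha = fit$rates$alpha, p_inv = fit$rates$p_inv,
                          k = fit$rates$k)
  manifest$n_substitutions <- subs$n_events
  manifest$n_retained <- if (inherits(report, "conservation_report"))
    report$n_retained else NA
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(fit = fit, reconstructions = recs, substitutions = subs,
                 conservation = report, identity = identity,
                 files = c(events = f_events, identity = f_ident,
                           manifest = file.path(cfg$out_dir, "manifest.json"))))
}

#' Run the structural stage of the pipeline
#'
#' Computes cavity reports for each configured structure, a ligand
#' molecular volume when ligand atoms are configured, a superposition
#' report when a pair is configured, pocket-lining residues, and, when an
#' events table from the evolution stage is supplied, per-candidate
#' pocket-proximity flags. Outputs and a manifest go to `config$out_dir`.
#'
#' Config keys: `structures` (list of `{name, path, chain,
#' keep_heteroatoms}`), `out_dir`; optional `cavity` (list of
#' [cavity_params()] arguments), `ligand` (`{structure, resid}` to measure
#' a bound ligand's volume), `superpose` (`{a, b, atom_scope}` by structure
#' name), `pocket` (`{structure, cutoff}`), `candidates` (`{events_tsv,
#' structure, cutoff}`), `seed`.
#'
#' @param config A validated configuration list.
#' @return Report list (cavities, ligand volume, superposition, pocket
#'   residues, candidate context, file paths), invisibly.
#' @export
run_structure_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  if (is.null(cfg$structures) || is.null(cfg$out_dir))
    stop("config must define structures and out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cav_args <- cfg$cavity %||% list()
  cav_args$seed <- cav_args$seed %||% cfg$seed %||% 1L
  params <- do.call(cavity_params, cav_args)

  structures <- list(); cavities <- list()
  for (s in cfg$structures) {
    st <- read_structure(s$path, chain = s$chain,
                         keep_heteroatoms = isTRUE(s$keep_heteroatoms))
    structures[[s$name]] <- st
    cav <- cavity_volume(st, params)
    cavities[[s$name]] <- cav
    jsonlite::write_json(
      list(structure = s$name, volumes = cav$volumes, mean = cav$mean,
           sd = cav$sd, no_cavity = cav$no_cavity,
           params = cfg$cavity %||% list()),
      file.path(cfg$out_dir, paste0("cavity_", s$name, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }

  ligand_volume <- NULL
  if (!is.null(cfg$ligand)) {
    st <- structures[[cfg$ligand$structure]]
    lig <- st$atoms[st$atoms$resid == cfg$ligand$resid, , drop = FALSE]
    if (nrow(lig) == 0L)
      stop("ligand residue '", cfg$ligand$resid, "' not found in structure '",
           cfg$ligand$structure, "' (was keep_heteroatoms set?)")
    lst <- structure(list(atoms = lig, source = cfg$ligand$resid),
                     class = "protein_structure")
    ligand_volume <- molecular_volume(lst, params)
    jsonlite::write_json(ligand_volume,
                         file.path(cfg$out_dir, "ligand_volume.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  superposition <- NULL
  if (!is.null(cfg$superpose)) {
    superposition <- superpose(structures[[cfg$superpose$a]],
                               structures[[cfg$superpose$b]],
                               atom_scope = cfg$superpose$atom_scope %||%
                                 "all-common")
    jsonlite::write_json(
      list(a = cfg$superpose$a, b = cfg$superpose$b,
           rmsd = superposition$rmsd,
           n_atom_pairs = superposition$n_atom_pairs,
           atom_scope = superposition$atom_scope,
           rotation = superposition$rotation,
           translation = superposition$translation),
      file.path(cfg$out_dir, "superposition.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }

  pocket <- NULL
  if (!is.null(cfg$pocket)) {
    nm <- cfg$pocket$structure
    pocket <- pocket_lining_residues(structures[[nm]], cavities[[nm]],
                                     cfg$pocket$cutoff %||% 3.5)
    utils::write.table(pocket,
                       file.path(cfg$out_dir, "pocket_residues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  candidates <- NULL
  if (!is.null(cfg$candidates)) {
    ev <- utils::read.delim(cfg$candidates$events_tsv)
    nm <- cfg$candidates$structure
    candidates <- candidate_structural_context(
      ev, structures[[nm]], cavity = cavities[[nm]],
      cutoff = cfg$candidates$cutoff %||% 5)
    utils::write.table(candidates,
                       file.path(cfg$out_dir, "candidate_context.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- manifest_entry(
    cfg, vapply(cfg$structures, `[[`, "", "path"), cav_args$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(structures = structures, cavities = cavities,
                 ligand_volume = ligand_volume,
                 superposition = superposition,
                 pocket = pocket, candidates = candidates,
                 out_dir = cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
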