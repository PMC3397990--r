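#' Construct a gene regulatory network topology
#'
#' A network is a set of genes, each contributing one mRNA and one protein
#' species, plus signed regulatory interactions: a regulator *protein* either
#' activates or represses transcription of a target gene through Hill
#' kinetics. Translation is mass action. Species are named `mRNA<gene>` and
#' `p<gene>`.
#'
#' @param genes character vector of gene identifiers (unique, non-empty).
#' @param interactions data frame with columns `from` (regulator gene whose
#'   protein acts), `to` (target gene) and `sign` (`"activation"` or
#'   `"repression"`). May have zero rows.
#' @param initial_conditions optional named numeric of starting
#'   concentrations per species; defaults to `1e-6` for every species (a
#'   small positive value: starting at exactly zero is numerically fragile
#'   for the sensitivity system).
#' @param basal optional named numeric of basal (regulator-independent)
#'   transcription rates per gene; default 0 for regulated genes.
#' @return object of class `gene_network`.
#' @examples
#' net <- gene_network(c("1", "2"),
#'   data.frame(from = "1", to = "2", sign = "repression"))
#' count_parameters(net)
#' @export
gene_network <- function(genes, interactions = NULL, initial_conditions = NULL,
                         basal = NULL) {
  genes <- as.character(genes)
  if (!length(genes) || !all(nzchar(genes)))
    stop("`genes` must be a non-empty vector of non-empty identifiers")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (is.null(interactions) || nrow(interactions) == 0) {
    interactions <- data.frame(from = character(), to = character(),
                               sign = character(), stringsAsFactors = FALSE)
  } else {
    interactions <- data.frame(from = as.character(interactions$from),
                               to = as.character(interactions$to),
                               sign = as.character(interactions$sign),
                               stringsAsFactors = FALSE)
  }
  if (!all(interactions$from %in% genes) || !all(interactions$to %in% genes))
    stop("interaction endpoints must be members of `genes`")
  if (!all(interactions$sign %in% c("activation", "repression")))
    stop("interaction sign must be 'activation' or 'repression'")
  if (anyDuplicated(interactions[c("from", "to")]))
    stop("duplicate (regulator, target) interaction")
  net <- structure(list(genes = genes, interactions = interactions),
                   class = "gene_network")
  sp <- species_names(net)
  x0 <- setNames(rep(1e-6, length(sp)), sp)
  if (!is.null(initial_conditions)) {
    unknown <- setdiff(names(initial_conditions), sp)
    if (length(unknown)) stop("unknown species in initial_conditions: ",
                              paste(unknown, collapse = ", "))
    x0[names(initial_conditions)] <- as.numeric(initial_conditions)
  }
  if (any(x0 < 0)) stop("initial conditions must be non-negative")
  b <- setNames(rep(0, length(genes)), genes)
  if (!is.null(basal)) {
    unknown <- setdiff(names(basal), genes)
    if (length(unknown)) stop("unknown genes in basal: ",
                              paste(unknown, collapse = ", "))
    b[names(basal)] <- as.numeric(basal)
  }
  net$initial_conditions <- x0
  net$basal <- b
  net$p_info <- compute_param_info(net)   # cached: hot path bookkeeping
  net$encoding <- net_encoding(net)
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$genes), "genes,",
      nrow(x$interactions), "interactions,",
      count_parameters(x), "free kinetic parameters\n")
  if (nrow(x$interactions)) {
    s <- ifelse(x$interactions$sign == "activation", "->", "-|")
    cat("  ", paste0("p", x$interactions$from, " ", s, " mRNA",
                     x$interactions$to, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Species names of a network
#'
#' @param network a [gene_network()].
#' @return character vector `c(mRNA<g>..., p<g>...)`, length `2 * G`.
#' @export
species_names <- function(network) {
  c(paste0("mRNA", network$genes), paste0("p", network$genes))
}

#' Number of free kinetic parameters
#'
#' Per gene one mRNA production strength and one ribosomal-binding-site
#' (translation) strength, one protein degradation rate shared by all
#' proteins, and per interaction one Hill coefficient and one Kd:
#' `2 * G + 1 + 2 * I`. mRNA degradation rates are fixed at 1 and not
#' counted.
#'
#' @param network a [gene_network()].
#' @return integer parameter count.
#' @export
count_parameters <- function(network) {
  2L * length(network$genes) + 1L + 2L * nrow(network$interactions)
}

#' Parameter bookkeeping for a network
#'
#' @param network a [gene_network()].
#' @return data frame with one row per free parameter: `name`, `type`
#'   (`production`, `rbs`, `delta_p`, `hill`, `kd`), `gene` (or `NA`),
#'   `interaction` (row index into `network$interactions`, or `NA`).
#' @export
param_info <- function(network) {
  if (!is.null(network$p_info)) return(network$p_info)
  compute_param_info(network)
}

compute_param_info <- function(network) {
  g <- network$genes
  ia <- network$interactions
  out <- data.frame(
    name = c(paste0("pro_", g), paste0("rbs_", g), "delta_p"),
    type = c(rep("production", length(g)), rep("rbs", length(g)), "delta_p"),
    gene = c(g, g, NA),
    interaction = NA_integer_,
    stringsAsFactors = FALSE)
  if (nrow(ia)) {
    lab <- paste0(ia$from, "_", ia$to)
    hill <- data.frame(
      name = as.vector(rbind(paste0("h_", lab), paste0("Kd_", lab))),
      type = rep(c("hill", "kd"), nrow(ia)),
      gene = NA_character_,
      interaction = rep(seq_len(nrow(ia)), each = 2),
      stringsAsFactors = FALSE)
    out <- rbind(out, hill)
  }
  out
}

#' Default parameter bounds on the log10 scale
#'
#' Non-Hill parameters span roughly five orders of magnitude,
#' `log10 theta` in `[-2, 3]`. Hill coefficients are restricted to `[1, 10]`
#' (`hill_range = "wide"`, the initial search box) or `[1, 8]`
#' (`hill_range = "narrow"`, the tightened box once profiles and direct
#' interaction measurements support it). Kd values use the non-Hill range.
#'
#' @param network a [gene_network()].
#' @param hill_range `"wide"` or `"narrow"`.
#' @param other numeric length-2, log10 bounds for non-Hill parameters.
#' @return list with numeric vectors `lower` and `upper` (log10 scale),
#'   named by parameter.
#' @export
default_bounds <- function(network, hill_range = c("wide", "narrow"),
                           other = c(-2, 3)) {
  hill_range <- match.arg(hill_range)
  hmax <- if (hill_range == "wide") 10 else 8
  info <- param_info(network)
  lower <- ifelse(info$type == "hill", 0, other[1])
  upper <- ifelse(info$type == "hill", log10(hmax), other[2])
  list(lower = setNames(lower, info$name), upper = setNames(upper, info$name))
}

# internal: integer encoding handed to the C++ kernels (0-based indices)
net_encoding <- function(network) {
  if (!is.null(network$encoding)) return(network$encoding)
  ia <- network$interactions
  list(G = length(network$genes),
       tg = match(ia$to, network$genes) - 1L,
       rg = match(ia$from, network$genes) - 1L,
       sg = ifelse(ia$sign == "activation", 1L, -1L))
}

# internal: validate/complete a linear-scale parameter vector
check_theta <- function(network, theta) {
  info <- param_info(network)
  if (is.null(names(theta))) {
    if (length(theta) != nrow(info))
      stop("parameter vector has length ", length(theta), ", expected ",
           nrow(info))
    names(theta) <- info$name
  } else {
    missing <- setdiff(info$name, names(theta))
    if (length(missing)) stop("missing parameters: ",
                              paste(missing, collapse = ", "))
    theta <- theta[info$name]
  }
  theta
}

#' Hill regulation rate
#'
#' Activation: `pro * (x/Kd)^h / (1 + (x/Kd)^h)`; repression:
#' `pro / (1 + (x/Kd)^h)`, where `x` is the regulator protein level.
#'
#' @param regulator_level protein concentration, `>= 0` (vectorized).
#' @param sign `"activation"` or `"repression"`.
#' @param h Hill coefficient (> 0).
#' @param Kd half-saturation constant (> 0).
#' @param production_strength maximal transcription rate (> 0).
#' @return transcription rate contribution.
#' @export
regulation_rate <- function(regulator_level, sign, h, Kd,
                            production_strength) {
  if (any(regulator_level < 0)) stop("negative regulator level")
  stopifnot(h > 0, Kd > 0, production_strength > 0)
  u <- (regulator_level / Kd)^h
  if (sign == "activation") production_strength * u / (1 + u)
  else if (sign == "repression") production_strength / (1 + u)
  else stop("sign must be 'activation' or 'repression'")
}

#' Transcription rate of one gene
#'
#' Unregulated genes transcribe at their constant production strength (plus
#' any basal rate). When several transcription factors act on a gene, the
#' Hill rate terms are summed, each scaled by the gene's single production
#' strength.
#'
#' @param network a [gene_network()].
#' @param gene gene identifier.
#' @param protein_levels named numeric of protein concentrations
#'   (names `p<gene>`), or unnamed in gene order.
#' @param theta linear-scale parameter vector (see [param_info()]).
#' @return transcription rate.
#' @export
transcription_rate <- function(network, gene, protein_levels, theta) {
  stopifnot(gene %in% network$genes)
  theta <- check_theta(network, theta)
  if (is.null(names(protein_levels)))
    names(protein_levels) <- paste0("p", network$genes)
  ia <- network$interactions
  rows <- which(ia$to == gene)
  pro <- theta[[paste0("pro_", gene)]]
  rate <- network$basal[[gene]]
  if (!length(rows)) return(rate + pro)
  for (j in rows) {
    lab <- paste0(ia$from[j], "_", ia$to[j])
    rate <- rate + regulation_rate(protein_levels[[paste0("p", ia$from[j])]],
                                   ia$sign[j], theta[[paste0("h_", lab)]],
                                   theta[[paste0("Kd_", lab)]], pro)
  }
  rate
}

#' Define an experimental perturbation
#'
#' Perturbations rewrite kinetic parameters before simulation: `knockout`
#' eliminates both production steps of a gene (mRNA production and rbs
#' strength set to 0), `sirna` raises the gene's mRNA degradation rate
#' five-fold, `rbs_boost` doubles the gene's translation strength and
#' `wildtype` changes nothing. Arbitrary extra rewrites (for prediction-only
#' conditions) multiply named parameters by given factors.
#'
#' @param kind one of `"wildtype"`, `"knockout"`, `"sirna"`, `"rbs_boost"`.
#' @param gene target gene; required unless `kind = "wildtype"`.
#' @param extra optional named numeric of (parameter name, multiplier).
#' @return object of class `perturbation`.
#' @export
perturbation <- function(kind = c("wildtype", "knockout", "sirna",
                                  "rbs_boost"),
                         gene = NULL, extra = NULL) {
  kind <- match.arg(kind)
  if (kind == "wildtype") {
    if (!is.null(gene)) stop("wildtype perturbation takes no gene")
  } else if (is.null(gene)) {
    stop("perturbation '", kind, "' requires a gene")
  }
  if (!is.null(extra) &&
      (is.null(names(extra)) || any(!nzchar(names(extra)))))
    stop("`extra` must be a named numeric of multipliers")
  structure(list(kind = kind, gene = if (!is.null(gene)) as.character(gene),
                 extra = extra),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("perturbation:", x$kind,
      if (!is.null(x$gene)) paste0("(gene ", x$gene, ")"), "\n")
  invisible(x)
}

#' @export
format.perturbation <- function(x, ...) {
  if (x$kind == "wildtype") "wildtype" else paste0(x$kind, "(", x$gene, ")")
}

#' Apply a perturbation to model parameters
#'
#' @param network a [gene_network()].
#' @param theta linear-scale parameter vector.
#' @param pert a [perturbation()].
#' @param dm per-gene mRNA degradation rates (fixed parameters, default 1).
#' @return list with rewritten `theta` (linear scale) and `dm`.
#' @export
apply_perturbation <- function(network, theta, pert,
                               dm = rep(1, length(network$genes))) {
  theta <- check_theta(network, theta)
  dm <- setNames(rep_len(dm, length(network$genes)), network$genes)
  if (!inherits(pert, "perturbation")) stop("`pert` must be a perturbation")
  if (!is.null(pert$gene) && !pert$gene %in% network$genes)
    stop("perturbation targets unknown gene: ", pert$gene)
  switch(pert$kind,
    wildtype = NULL,
    knockout = {
      theta[[paste0("pro_", pert$gene)]] <- 0
      theta[[paste0("rbs_", pert$gene)]] <- 0
    },
    sirna = { dm[[pert$gene]] <- 5 * dm[[pert$gene]] },
    rbs_boost = {
      theta[[paste0("rbs_", pert$gene)]] <- 2 * theta[[paste0("rbs_", pert$gene)]]
    })
  if (!is.null(pert$extra)) {
    unknown <- setdiff(names(pert$extra), names(theta))
    if (length(unknown)) stop("extra rewrite targets unknown parameters: ",
                              paste(unknown, collapse = ", "))
    theta[names(pert$extra)] <- theta[names(pert$extra)] * pert$extra
  }
  list(theta = theta, dm = dm)
}

#' Build the ODE right-hand side of a network
#'
#' Returns the autonomous vector field `f(x)` of the transcription /
#' translation system: `d mRNA_g/dt = transcription - dm_g * mRNA_g`,
#' `d protein_g/dt = rbs_g * mRNA_g - delta_p * protein_g`, with the
#' perturbation's parameter rewrites applied first. The returned closure
#' carries the compiled-model encoding, so [integrate_ode()] dispatches to
#' the fast C++ path.
#'
#' @inheritParams apply_perturbation
#' @return function `f(x)` of class `grn_rhs`; `x` may be named by species.
#' @export
build_rhs <- function(network, theta, pert = perturbation("wildtype"),
                      dm = rep(1, length(network$genes))) {
  pp <- apply_perturbation(network, theta, pert, dm)
  enc <- net_encoding(network)
  sp <- species_names(network)
  f <- function(x) {
    if (!is.null(names(x))) x <- x[sp]
    if (length(x) != length(sp) || anyNA(x))
      stop("state has wrong length or unknown species")
    setNames(grn_rhs_cpp(enc$G, enc$tg, enc$rg, enc$sg, unname(pp$theta),
                         unname(pp$dm), unname(network$basal), as.numeric(x)),
             sp)
  }
  structure(f, class = c("grn_rhs", "function"), network = network,
            theta = pp$theta, dm = pp$dm, encoding = enc)
}

#' Read a network description from JSON
#'
#' Expected shape:
#' `{"genes": [...], "interactions": [{"from":, "to":, "sign":}, ...],`
#' `"initial_conditions": {...}, "basal": {...}}` (the last two optional).
#'
#' @param path file path.
#' @return a [gene_network()].
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ia <- x$interactions
  if (is.null(ia) || (is.data.frame(ia) && !nrow(ia))) ia <- NULL
  gene_network(as.character(x$genes), ia,
               initial_conditions = unlist(x$initial_conditions),
               basal = unlist(x$basal))
}

#' Write a network description to JSON
#'
#' @param network a [gene_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(
    list(genes = network$genes, interactions = network$interactions,
         initial_conditions = as.list(network$initial_conditions),
         basal = as.list(network$basal)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
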