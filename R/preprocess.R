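#' Orthogroup-by-sample expression dataset
#'
#' The common currency of all analysis stages: a non-negative integer
#' orthogroup-by-sample count matrix plus a sample table with exactly one
#' species, clade and phenotype per sample.
#'
#' @param counts integer matrix, rows = orthogroups, columns = sample ids.
#' @param samples data.frame with columns `sample_id`, `species`, `clade`,
#'   `phenotype` (values `reproductive` / `non_reproductive`).
#' @param provenance free-form list recording source paths and filter log.
#' @return an object of class `ortho_dataset`.
#' @export
ortho_dataset <- function(counts, samples, provenance = list()) {
  stopifnot(is.matrix(counts),
            all(c("sample_id", "species", "clade", "phenotype") %in%
                  names(samples)))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id))
    counts <- counts[, samples$sample_id, drop = FALSE]
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  all_na <- apply(counts, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    counts <- counts[!all_na, , drop = FALSE]
    provenance$dropped_all_missing <- sum(all_na)
  }
  bad <- !samples$phenotype %in% c("reproductive", "non_reproductive")
  if (any(bad)) stop("phenotype must be reproductive/non_reproductive")
  structure(list(counts = counts, samples = samples,
                 provenance = provenance),
            class = "ortho_dataset")
}

#' @export
print.ortho_dataset <- function(x, ...) {
  cat(sprintf("ortho_dataset: %d orthogroups x %d samples, %d species (%s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$species)),
              paste(unique(x$samples$clade), collapse = "/")))
  invisible(x)
}

#' Column indices of one species' samples
#' @param dataset an `ortho_dataset`.
#' @param species species label.
#' @export
species_columns <- function(dataset, species) {
  which(dataset$samples$species == species)
}

#' Orthology filtering policy
#'
#' Retains orthogroups with at most `max_copies_per_species` gene copies in
#' any species and absent in at most `max_absent_species` species — the
#' relaxed "nearly single-copy" rule appropriate for clades separated by
#' ~200 My.
#'
#' @param max_copies_per_species maximum gene copies per species (default 3).
#' @param max_absent_species maximum species an orthogroup may be absent
#'   from (default 1).
#' @param multi_copy_reduction how within-species copies are collapsed when
#'   assembling the matrix: `"sum"` (default; preserves library-size
#'   accounting), `"max"` or `"mean"`.
#' @export
ortho_filter_policy <- function(max_copies_per_species = 3,
                                max_absent_species = 1,
                                multi_copy_reduction = c("sum", "max", "mean")) {
  stopifnot(max_copies_per_species >= 1, max_absent_species >= 0)
  structure(list(max_copies_per_species = max_copies_per_species,
                 max_absent_species = max_absent_species,
                 multi_copy_reduction = match.arg(multi_copy_reduction)),
            class = "ortho_filter_policy")
}

#' Read a per-species counts TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' @param path file path.
#' @return integer matrix with gene-id rownames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id in ", path, ": ",
         ids[duplicated(ids)][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed counts (non-numeric cells) in ", path)
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  m
}

#' Read the sample metadata TSV
#'
#' @param path file path; requires columns `sample_id`, `species`, `clade`,
#'   `phenotype`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "clade", "phenotype")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' Read an OrthoFinder-style Orthogroups.tsv under a filtering policy
#'
#' Column 1 is the orthogroup id; each further column holds one species'
#' comma-space-separated gene ids (empty when absent). Orthogroups violating
#' the policy are dropped and logged with a reason (`"copy_number"` or
#' `"absence"`).
#'
#' @param path file path.
#' @param policy an [ortho_filter_policy()].
#' @return list with `map` (orthogroup -> species -> character gene ids, in
#'   input order) and `log` (data.frame of dropped orthogroups and reasons).
#' @export
read_orthogroups <- function(path, policy = ortho_filter_policy()) {
  if (!file.exists(path)) stop("orthogroups file not found: ", path)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  og_ids <- d[[1]]
  species <- names(d)[-1]
  map <- list()
  log <- data.frame(orthogroup = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(og_ids)) {
    genes <- lapply(species, function(s) {
      cell <- d[i, s]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",")[[1]])
    })
    names(genes) <- species
    copies <- vapply(genes, length, 1L)
    if (any(copies > policy$max_copies_per_species)) {
      log <- rbind(log, data.frame(orthogroup = og_ids[i],
                                   reason = "copy_number"))
    } else if (sum(copies == 0) > policy$max_absent_species) {
      log <- rbind(log, data.frame(orthogroup = og_ids[i],
                                   reason = "absence"))
    } else {
      map[[og_ids[i]]] <- genes
    }
  }
  list(map = map, log = log)
}

#' Assemble the orthogroup-by-sample matrix from per-species counts
#'
#' One row per retained orthogroup; within-species multi-copy genes are
#' collapsed by the policy's reduction rule. Species where the orthogroup is
#' absent (allowed by the policy) get `NA` in their columns.
#'
#' @param counts_by_species named list of per-species count matrices
#'   (species-local gene ids).
#' @param ortho the `map` element of [read_orthogroups()] (or the whole
#'   return value).
#' @param metadata sample metadata data.frame.
#' @param policy an [ortho_filter_policy()].
#' @return an [ortho_dataset()].
#' @export
assemble_ortho_matrix <- function(counts_by_species, ortho, metadata,
                                  policy = ortho_filter_policy()) {
  if (!is.null(ortho$map)) ortho <- ortho$map
  species <- names(counts_by_species)
  for (s in species) {
    ids <- colnames(counts_by_species[[s]])
    missing_meta <- setdiff(ids, metadata$sample_id)
    if (length(missing_meta))
      stop("samples in counts absent from metadata: ",
           paste(missing_meta, collapse = ", "))
  }
  metadata <- metadata[metadata$sample_id %in%
                         unlist(lapply(counts_by_species, colnames)), ]
  reduce <- switch(policy$multi_copy_reduction,
                   sum = colSums, max = function(m) apply(m, 2, max),
                   mean = colMeans)
  filter_log <- character(0)
  rows <- lapply(names(ortho), function(og) {
    vals <- lapply(species, function(s) {
      g <- intersect(ortho[[og]][[s]], rownames(counts_by_species[[s]]))
      ncol_s <- ncol(counts_by_species[[s]])
      if (length(g) == 0) {
        if (length(ortho[[og]][[s]]) > 0)
          filter_log <<- c(filter_log,
                           sprintf("%s: no mappable genes in %s", og, s))
        return(rep(NA_real_, ncol_s))
      }
      m <- counts_by_species[[s]][g, , drop = FALSE]
      if (nrow(m) == 1) as.numeric(m) else as.numeric(reduce(m))
    })
    unlist(vals)
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- names(ortho)
  colnames(counts) <- unlist(lapply(counts_by_species, colnames))
  # drop rows whose realized missingness violates the policy
  n_absent <- apply(counts, 1, function(r) {
    sum(vapply(species, function(s) {
      cols <- which(colnames(counts) %in%
                      metadata$sample_id[metadata$species == s])
      all(is.na(r[cols]))
    }, TRUE))
  })
  keep <- n_absent <= policy$max_absent_species
  if (any(!keep))
    filter_log <- c(filter_log,
                    sprintf("%s: dropped, absent in %d species",
                            rownames(counts)[!keep], n_absent[!keep]))
  counts <- round(counts[keep, , drop = FALSE])
  storage.mode(counts) <- "integer"
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  ortho_dataset(counts, metadata,
                provenance = list(filter_log = filter_log))
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in all samples, the factor of sample j is
#' the median of `count_gj / geomean_g`. Falls back (with a warning) to
#' total-count ratios when no gene is expressed everywhere.
#'
#' @param counts orthogroup-by-sample count matrix (`NA` rows tolerated).
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  cc <- counts[stats::complete.cases(counts), , drop = FALSE]
  pos <- cc[apply(cc, 1, function(r) all(r > 0)), , drop = FALSE]
  if (nrow(pos) == 0) {
    warning("no gene expressed in all samples; using total-count ratios")
    tot <- colSums(cc, na.rm = TRUE)
    return(tot / exp(mean(log(tot))))
  }
  logg <- rowMeans(log(pos))
  apply(pos, 2, function(cnt) exp(median(log(cnt) - logg)))
}

#' Closed-form variance-stabilizing transform for NB counts
#'
#' Applies \eqn{g(q) = \log_2\frac{1 + a_1 + 2 a_0 q +
#' 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}} to size-factor-normalized counts
#' `q`, where the parametric dispersion trend is
#' \eqn{\alpha(\mu) = a_0/\mu + a_1}. With `species_aware = TRUE` the trend
#' is fitted on dispersions estimated from within-species residuals (a
#' species-mean model), so between-species expression shifts do not inflate
#' the fitted dispersion.
#'
#' @param dataset an `ortho_dataset` (or a bare counts matrix plus
#'   `samples`).
#' @param species_aware fit the dispersion trend on within-species residual
#'   dispersions (default `TRUE`).
#' @param sf optional precomputed size factors.
#' @return a `normalized_matrix`: list with `values`, `transform`
#'   (`"vst"` or `"log_size_factor"` on trend-fit failure), `species_aware`,
#'   `centered`, `size_factors`, `dispersion_trend`.
#' @export
variance_stabilize <- function(dataset, species_aware = TRUE, sf = NULL) {
  counts <- dataset$counts
  samples <- dataset$samples
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q, na.rm = TRUE)
  inv_sf_mean <- mean(1 / sf)
  if (species_aware) {
    sp <- samples$species
    ss <- 0; df <- 0
    for (s in unique(sp)) {
      qs <- q[, sp == s, drop = FALSE]
      ns <- ncol(qs)
      if (ns >= 2) {
        ss <- ss + apply(qs, 1, function(r) sum((r - mean(r))^2, na.rm = TRUE))
        df <- df + (ns - 1)
      }
    }
    v <- ss / df
  } else {
    v <- apply(q, 1, var, na.rm = TRUE)
  }
  disp <- (v - mu * inv_sf_mean) / mu^2
  use <- is.finite(disp) & disp > 0 & mu > 1
  # parametric trend alpha(mu) = asympt + extra_pois / mu, fitted by
  # trimmed least squares of moment dispersions against 1/mu
  trend <- c(asympt = NA_real_, extra_pois = NA_real_)
  if (sum(use) >= 10) {
    fit <- lm(disp[use] ~ I(1 / mu[use]))
    res <- abs(stats::residuals(fit))
    keep <- res <= quantile(res, 0.9)
    fit <- lm(disp[use][keep] ~ I(1 / mu[use][keep]))
    trend <- c(asympt = unname(coef(fit)[1]),
               extra_pois = unname(coef(fit)[2]))
  }
  if (!is.finite(trend["asympt"]) || trend["asympt"] <= 0) {
    warning("dispersion trend fit failed (asymptotic dispersion <= 0); ",
            "using log2(q + 1)")
    return(structure(list(values = log2(q + 1), transform = "log_size_factor",
                          species_aware = species_aware, centered = FALSE,
                          size_factors = sf, dispersion_trend = trend,
                          samples = samples),
                     class = "normalized_matrix"))
  }
  trend["extra_pois"] <- max(trend["extra_pois"], 0)
  a <- trend["asympt"]; b <- trend["extra_pois"]
  # closed form of integral dq / sqrt(q (1 + b) + a q^2)
  g <- function(x) log2((1 + b + 2 * a * x +
                           2 * sqrt(a * x * (1 + b + a * x))) / (4 * a))
  structure(list(values = g(q), transform = "vst",
                 species_aware = species_aware, centered = FALSE,
                 size_factors = sf, dispersion_trend = trend,
                 samples = samples),
            class = "normalized_matrix")
}

#' Center (and scale) each gene row
#'
#' @param nm a `normalized_matrix` (or bare matrix).
#' @param scope `"global"` or `"per_species"`; per-species centering removes
#'   species-level expression shifts and is the species-aware input the SVM
#'   stage expects.
#' @param scale divide by the row sd within scope (default `TRUE`).
#' @return the input with centered (and unit-sd) rows; constant rows are set
#'   to 0 and flagged in `attr(values, "constant_rows")`.
#' @export
center_scale <- function(nm, scope = c("global", "per_species"),
                         scale = TRUE) {
  scope <- match.arg(scope)
  bare <- !inherits(nm, "normalized_matrix")
  values <- if (bare) nm else nm$values
  samples <- if (bare) NULL else nm$samples
  do_block <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    m <- m - mu
    flagged <- rep(FALSE, nrow(m))
    if (scale) {
      s <- apply(m, 1, sd, na.rm = TRUE)
      flagged <- !is.finite(s) | s < 1e-12
      s[flagged] <- 1
      m <- m / s
      m[flagged, ] <- 0
    }
    list(m = m, flagged = flagged)
  }
  if (scope == "global" || is.null(samples)) {
    r <- do_block(values)
    values <- r$m
    flagged <- r$flagged
  } else {
    flagged <- rep(FALSE, nrow(values))
    for (s in unique(samples$species)) {
      cols <- samples$species == s
      r <- do_block(values[, cols, drop = FALSE])
      values[, cols] <- r$m
      flagged <- flagged | r$flagged
    }
  }
  attr(values, "constant_rows") <- rownames(values)[flagged]
  if (bare) return(values)
  nm$values <- values
  nm$centered <- TRUE
  nm$center_scope <- scope
  nm
}
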