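#' Molecular system container
#'
#' A `molecular_system` bundles the static side of every computation: one row
#' per atom with identity (serial, name, element, residue, chain), nonbonded
#' parameters (partial charge in e, Lennard-Jones sigma in nm and epsilon in
#' kJ/mol), mass (amu) and a domain label (e.g. `Cat`, `Fib`, `Hpx`, `Lnk`,
#' `ion`, `solvent`, `other`).
#'
#' @param atoms A data frame with columns `serial`, `name`, `element`,
#'   `resid`, `resname`, `chain`, `charge`, `sigma`, `epsilon`, `mass`,
#'   `domain`. Missing parameter columns default to zero, missing `domain`
#'   to `"other"`.
#' @return An object of class `molecular_system`; `$atoms` is a tibble.
#' @export
molecular_system <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("serial", "name", "element", "resid", "resname", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"sigma" %in% names(atoms)) atoms$sigma <- 0
  if (!"epsilon" %in% names(atoms)) atoms$epsilon <- 0
  if (!"mass" %in% names(atoms)) atoms$mass <- .element_mass(atoms$element)
  if (!"domain" %in% names(atoms)) atoms$domain <- "other"
  if (any(!is.finite(atoms$charge))) stop("non-finite charges")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0)) {
    stop("Lennard-Jones sigma and epsilon must be non-negative")
  }
  structure(list(atoms = atoms), class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<molecular_system> %d atoms, %d residues, domains: %s\n",
    nrow(a), length(unique(paste(a$chain, a$resid))),
    paste(sort(unique(a$domain)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of atoms in a system
#' @param system A `molecular_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Read a nonbonded parameter table
#'
#' Plain-text whitespace/tab separated columns: `resname`, `name`, `charge`
#' (e), `sigma` (nm), `epsilon` (kJ/mol). A `resname` of `*` matches any
#' residue and acts as a per-atom-name fallback.
#'
#' @param path Path to the table.
#' @return A tibble with the five columns.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  # na.strings empty so the sodium resname "NA" survives as a literal string
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, na.strings = character(0))
  need <- c("resname", "name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(tab[, need])
}

#' Read a domain definition config
#'
#' YAML with a `domains` map of `label: [first, last]` residue ranges
#' (1-based author numbering, inclusive on both ends), optional `ion_names`
#' (residue/atom names treated as ions), `equilibration_ns` (analysis window
#' start) and `stride_ns` (sampling interval).
#'
#' @param path Path to a YAML file.
#' @return A list of class `domain_config`.
#' @export
read_domain_config <- function(path) {
  if (!file.exists(path)) stop("domain config not found: ", path)
  cfg <- yaml::read_yaml(path)
  domain_config(
    domains = lapply(cfg$domains, function(r) as.integer(r)),
    ion_names = cfg$ion_names %||% c("ZN", "CA"),
    equilibration_ns = cfg$equilibration_ns %||% 0,
    stride_ns = cfg$stride_ns %||% NA_real_
  )
}

#' Construct a domain config in code
#'
#' @param domains Named list of integer length-2 vectors `(first, last)`,
#'   residue ranges inclusive on both ends.
#' @param ion_names Residue names to label as `ion`.
#' @param equilibration_ns Time (ns) before which frames are discarded from
#'   analysis windows.
#' @param stride_ns Sampling interval (ns), informational.
#' @return A list of class `domain_config`.
#' @export
domain_config <- function(domains, ion_names = c("ZN", "CA"),
                          equilibration_ns = 0, stride_ns = NA_real_) {
  stopifnot(equilibration_ns >= 0)
  for (d in domains) {
    if (length(d) != 2 || d[1] > d[2]) stop("domain ranges must be (first, last)")
  }
  structure(list(domains = domains, ion_names = ion_names,
                 equilibration_ns = equilibration_ns, stride_ns = stride_ns),
            class = "domain_config")
}

# Assign a domain label to each atom from config ranges + special residues.
.assign_domains <- function(atoms, config) {
  domain <- rep("other", nrow(atoms))
  if (!is.null(config)) {
    # Later entries win where ranges overlap (e.g. Fib inserted within Cat),
    # so list the inserted domain after its host in the config.
    for (lab in names(config$domains)) {
      r <- config$domains[[lab]]
      hit <- atoms$resid >= r[1] & atoms$resid <= r[2] & !.is_nonprotein(atoms)
      domain[hit] <- lab
    }
    ion_hit <- atoms$resname %in% config$ion_names & .is_het_ion(atoms)
    domain[ion_hit] <- "ion"
  } else {
    domain[.is_het_ion(atoms)] <- "ion"
  }
  domain[atoms$resname %in% c("HOH", "SOL", "WAT", "TIP3", "TIP3M")] <- "solvent"
  domain
}

.is_het_ion <- function(atoms) {
  atoms$resname %in% c("ZN", "CA", "MG", "NA", "CL", "K") &
    toupper(atoms$name) == toupper(atoms$resname)
}

.is_nonprotein <- function(atoms) {
  .is_het_ion(atoms) | atoms$resname %in% c("HOH", "SOL", "WAT", "TIP3", "TIP3M")
}

# His protonation-variant aliasing applied at load.
.canonical_resname <- function(resname) {
  alias <- c(HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS", HIE = "HIS",
             HIP = "HIS")
  out <- alias[resname]
  ifelse(is.na(out), resname, out)
}

.guess_element <- function(name, resname) {
  name <- toupper(name)
  two <- name %in% c("ZN", "CA", "NA", "CL", "MG", "FE", "BR") &
    resname %in% c("ZN", "CA", "NA", "CL", "MG", "FE", "BR")
  el <- substr(gsub("^[0-9]+", "", name), 1, 1)
  ifelse(two, name, el)
}

#' Load a molecular system from a PDB file
#'
#' Parses the structure with \pkg{bio3d}, aliases His protonation variants,
#' labels domains from the config, and attaches nonbonded parameters by
#' `(resname, name)` lookup with a `(*, name)` wildcard fallback. Divalent
#' ions named ZN/CA get formal charge +2 and the Lennard-Jones parameters
#' from the table. Atoms with no parameters and no fallback are a hard error
#' unless `fallback = TRUE`, in which case they get zero charge and
#' element-generic LJ values and are listed in the `unresolved` attribute.
#'
#' @param structure_file Path to a PDB file.
#' @param parameter_table Path to a parameter table
#'   (see [read_parameter_table()]), or a data frame.
#' @param domain_config Path to a YAML domain config, a `domain_config`, or
#'   `NULL`.
#' @param fallback Use element-generic parameters for unmatched atoms instead
#'   of erroring.
#' @return A `molecular_system` with attribute `unresolved` (character vector
#'   of atoms that used the fallback) and attribute `coords` (matrix of the
#'   structure's coordinates, nm).
#' @export
load_system <- function(structure_file, parameter_table = NULL,
                        domain_config = NULL, fallback = TRUE) {
  if (!file.exists(structure_file)) stop("structure file not found: ", structure_file)
  pdb <- bio3d::read.pdb(structure_file, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = ifelse(!is.null(at$elesy) & nzchar(trimws(at$elesy %||% "")),
                     trimws(at$elesy), .guess_element(at$elety, at$resid)),
    resid = as.integer(at$resno),
    resname = .canonical_resname(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain)
  )
  atoms$element[!nzchar(atoms$element)] <-
    .guess_element(atoms$name, atoms$resname)[!nzchar(atoms$element)]
  atoms$mass <- .element_mass(atoms$element)

  cfg <- domain_config
  if (is.character(cfg)) cfg <- read_domain_config(cfg)
  atoms$domain <- .assign_domains(atoms, cfg)

  params <- parameter_table
  if (is.character(params)) params <- read_parameter_table(params)
  unresolved <- character(0)
  atoms$charge <- 0
  atoms$sigma <- 0
  atoms$epsilon <- 0
  if (!is.null(params)) {
    key <- paste(atoms$resname, atoms$name)
    pkey <- paste(params$resname, params$name)
    idx <- match(key, pkey)
    wkey <- paste("*", atoms$name)
    widx <- match(wkey, pkey)
    use <- ifelse(is.na(idx), widx, idx)
    hit <- !is.na(use)
    atoms$charge[hit] <- params$charge[use[hit]]
    atoms$sigma[hit] <- params$sigma[use[hit]]
    atoms$epsilon[hit] <- params$epsilon[use[hit]]
    unresolved <- unique(key[!hit])
    if (length(unresolved) > 0 && !fallback) {
      stop("no parameters for atom(s): ", paste(unresolved, collapse = "; "))
    }
  }
  # Formal +2 for divalent cations regardless of table contents.
  div <- .is_het_ion(atoms) & atoms$resname %in% c("ZN", "CA", "MG")
  atoms$charge[div] <- 2

  sys <- molecular_system(atoms)
  attr(sys, "unresolved") <- unresolved
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  attr(sys, "coords") <- xyz
  attr(sys, "cryst1") <- .read_cryst1(structure_file)
  sys
}

.read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 500, warn = FALSE), value = TRUE)
  if (length(ln) == 0) return(NULL)
  as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
               substr(ln[1], 25, 33))) / 10  # a, b, c in nm
}

#' Select atoms by expression
#'
#' Small selection language over the atom table: terms are
#' `name <v>`, `resname <v>`, `element <v>`, `chain <v>`, `domain <v>`,
#' `resid <a>-<b>` (inclusive range) or `resid <v1>,<v2>,...`; values may be
#' comma-separated lists. Terms combine with `and`, `or`, `not` and
#' parentheses. `all` matches everything. Selection is deterministic: indices
#' are returned sorted ascending, so repeated calls are order-stable.
#'
#' @param system A `molecular_system`.
#' @param expression Selection string, e.g. `"name CA and domain Cat"`.
#' @return Sorted integer vector of atom indices (1-based rows of
#'   `system$atoms`); may be empty.
#' @export
select_atoms <- function(system, expression) {
  atoms <- system$atoms
  toks <- .tokenize_selection(expression)
  res <- .parse_or(toks, atoms)
  if (length(res$tokens) != 0) {
    stop("malformed selection near: ", paste(res$tokens, collapse = " "))
  }
  sort(which(res$mask))
}

.tokenize_selection <- function(expression) {
  expression <- gsub("\\(", " ( ", expression)
  expression <- gsub("\\)", " ) ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (length(toks) == 0 || !nzchar(toks[1])) stop("empty selection expression")
  toks
}

.parse_or <- function(tokens, atoms) {
  left <- .parse_and(tokens, atoms)
  while (length(left$tokens) > 0 && tolower(left$tokens[1]) == "or") {
    right <- .parse_and(left$tokens[-1], atoms)
    left <- list(mask = left$mask | right$mask, tokens = right$tokens)
  }
  left
}

.parse_and <- function(tokens, atoms) {
  left <- .parse_unary(tokens, atoms)
  while (length(left$tokens) > 0 && tolower(left$tokens[1]) == "and") {
    right <- .parse_unary(left$tokens[-1], atoms)
    left <- list(mask = left$mask & right$mask, tokens = right$tokens)
  }
  left
}

.parse_unary <- function(tokens, atoms) {
  if (length(tokens) == 0) stop("malformed selection: unexpected end")
  if (tolower(tokens[1]) == "not") {
    res <- .parse_unary(tokens[-1], atoms)
    return(list(mask = !res$mask, tokens = res$tokens))
  }
  if (tokens[1] == "(") {
    res <- .parse_or(tokens[-1], atoms)
    if (length(res$tokens) == 0 || res$tokens[1] != ")") {
      stop("malformed selection: unbalanced parentheses")
    }
    return(list(mask = res$mask, tokens = res$tokens[-1]))
  }
  .parse_term(tokens, atoms)
}

.parse_term <- function(tokens, atoms) {
  kw <- tolower(tokens[1])
  if (kw == "all") return(list(mask = rep(TRUE, nrow(atoms)), tokens = tokens[-1]))
  if (!kw %in% c("name", "resname", "element", "chain", "domain", "resid")) {
    stop("malformed selection: unknown keyword '", tokens[1], "'")
  }
  if (length(tokens) < 2) stop("malformed selection: '", kw, "' needs a value")
  value <- tokens[2]
  rest <- tokens[-(1:2)]
  if (kw == "resid") {
    if (grepl("-|:", value)) {
      ab <- as.integer(strsplit(value, "-|:")[[1]])
      if (length(ab) != 2 || any(is.na(ab))) stop("bad resid range: ", value)
      mask <- atoms$resid >= ab[1] & atoms$resid <= ab[2]
    } else {
      ids <- as.integer(strsplit(value, ",")[[1]])
      if (any(is.na(ids))) stop("bad resid list: ", value)
      mask <- atoms$resid %in% ids
    }
  } else {
    vals <- toupper(strsplit(value, ",")[[1]])
    col <- atoms[[kw]]
    mask <- toupper(col) %in% vals
  }
  list(mask = mask, tokens = rest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
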