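#' Default functional-class labels for epigenetic regulators
#'
#' Eight broad classes spanning the writer/reader/eraser and structural arms
#' of the epigenetic regulatory network. The labels are configurable
#' everywhere they are used; this vector only supplies defaults.
#'
#' @export
ern_classes <- function() {
  c(
    "lysine acetylation",
    "lysine methylation",
    "chromatin remodeling",
    "histone variants & chaperones",
    "genome topology",
    "DNA methylation",
    "ubiquitination/other modifier",
    "reader/eraser"
  )
}

#' Build an annotated target-gene library
#'
#' Constructs a gene library of the kind used in arrayed knockout fitness
#' screens: `n_targets` target genes partitioned over functional classes, a
#' fraction of them annotated with a paralogue partner, plus one designated
#' negative-control gene (a non-expressed gene such as *TNP2*) that is later
#' replicated across control wells.
#'
#' @param n_targets Number of target genes (default 200).
#' @param classes Character vector of functional-class labels.
#' @param class_weights Optional non-negative weights, one per class, giving
#'   the relative class sizes. Default: equal weights.
#' @param paralogue_fraction Fraction of targets annotated as having a
#'   paralogue partner (default 0.4).
#' @param control_gene Symbol of the negative-control gene (default `"TNP2"`).
#' @param seed Optional integer seed making paralogue assignment reproducible.
#'
#' @return A tibble with class `ern_library` and columns `gene_id`,
#'   `functional_class`, `has_paralogue`, `paralogue_partner`,
#'   `expression_tpm`, `is_negative_control`. The control gene carries no
#'   functional class. `n_targets` counts non-control rows.
#' @export
build_default_library <- function(n_targets = 200,
                                  classes = ern_classes(),
                                  class_weights = NULL,
                                  paralogue_fraction = 0.4,
                                  control_gene = "TNP2",
                                  seed = NULL) {
  stopifnot(n_targets >= 0, length(classes) >= 1)
  class_weights <- class_weights %||% rep(1, length(classes))
  if (length(class_weights) != length(classes) || any(class_weights < 0)) {
    abort("`class_weights` must be non-negative, one per class.")
  }

  if (n_targets == 0) {
    genes <- tibble(
      gene_id = character(), functional_class = character(),
      has_paralogue = logical(), paralogue_partner = character(),
      expression_tpm = double(), is_negative_control = logical()
    )
  } else {
    # largest-remainder apportionment of targets across classes
    raw <- n_targets * class_weights / sum(class_weights)
    sizes <- floor(raw)
    rem <- n_targets - sum(sizes)
    if (rem > 0) {
      top <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1
    }
    cls <- rep(classes, times = sizes)
    ids <- sprintf("ERG%03d", seq_len(n_targets))

    assign_paralogues <- function() {
      n_para <- round(paralogue_fraction * n_targets)
      n_para <- n_para - (n_para %% 2)  # paired partners
      partner <- rep(NA_character_, n_targets)
      if (n_para >= 2) {
        idx <- sample.int(n_targets, n_para)
        a <- idx[seq(1, n_para, by = 2)]
        b <- idx[seq(2, n_para, by = 2)]
        partner[a] <- ids[b]
        partner[b] <- ids[a]
      }
      partner
    }
    partner <- if (is.null(seed)) assign_paralogues() else with_seed(seed, assign_paralogues())

    genes <- tibble(
      gene_id = ids,
      functional_class = cls,
      has_paralogue = !is.na(partner),
      paralogue_partner = partner,
      expression_tpm = NA_real_,
      is_negative_control = FALSE
    )
  }

  out <- bind_rows(
    genes,
    tibble(
      gene_id = control_gene, functional_class = NA_character_,
      has_paralogue = FALSE, paralogue_partner = NA_character_,
      expression_tpm = 0, is_negative_control = TRUE
    )
  )
  validate_library(out)
}

#' @rdname build_default_library
#' @param library A library tibble to validate.
#' @export
validate_library <- function(library) {
  stopifnot(is.data.frame(library))
  req <- c("gene_id", "functional_class", "has_paralogue",
           "paralogue_partner", "is_negative_control")
  missing_cols <- setdiff(req, names(library))
  if (length(missing_cols)) {
    abort(paste0("Library is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(library$gene_id)) || any(!nzchar(library$gene_id))) {
    abort("gene_id must be non-empty.")
  }
  if (anyDuplicated(library$gene_id)) abort("gene_id must be unique within a library.")
  if (any(!is.na(library$functional_class[library$is_negative_control]))) {
    abort("Negative controls must not carry a functional class.")
  }
  if (any(library$has_paralogue != !is.na(library$paralogue_partner))) {
    abort("has_paralogue must be TRUE exactly when paralogue_partner is set.")
  }
  out <- as_tibble(library)
  class(out) <- unique(c("ern_library", class(out)))
  out
}

#' Number of non-control target genes in a library
#' @param library A library tibble.
#' @export
n_targets <- function(library) sum(!library$is_negative_control)

#' Drop targets that are unexpressed in any assayed cell line
#'
#' Restricts a library to genes whose expression meets `threshold` in every
#' supplied cell line, mirroring the pre-screen filter that removes genes
#' unexpressed in either model. The negative-control gene is unexpressed by
#' design and is only kept when `exempt_controls = TRUE`.
#'
#' @param library An `ern_library` tibble.
#' @param tpm_table Tibble with columns `gene_id` and one `tpm_*` (or any
#'   additional numeric) column per cell line.
#' @param threshold Minimum TPM required in every line (default 1).
#' @param exempt_controls Keep negative-control genes regardless of
#'   expression (default TRUE).
#' @param strict If TRUE (default), a target gene absent from `tpm_table` is
#'   an error; if FALSE it is dropped with a warning.
#'
#' @return The filtered library.
#' @export
filter_unexpressed <- function(library, tpm_table, threshold = 1,
                               exempt_controls = TRUE, strict = TRUE) {
  library <- validate_library(library)
  stopifnot(is.data.frame(tpm_table), "gene_id" %in% names(tpm_table))
  tpm_cols <- setdiff(names(tpm_table), "gene_id")
  if (!length(tpm_cols)) abort("`tpm_table` has no expression columns.")

  targets <- library$gene_id[!library$is_negative_control]
  absent <- setdiff(targets, tpm_table$gene_id)
  if (length(absent)) {
    msg <- paste0("Genes missing from tpm_table: ", paste(absent, collapse = ", "))
    if (strict) abort(msg) else warn(paste0(msg, " (dropped)"))
  }

  # expressed = meets the threshold in every line and is never exactly zero,
  # so a threshold of 0 still removes unexpressed (TPM = 0) genes
  expressed <- tpm_table$gene_id[
    apply(as.matrix(tpm_table[tpm_cols]), 1,
          function(x) all(!is.na(x) & x >= threshold & x > 0))
  ]
  keep <- library$gene_id %in% expressed |
    (exempt_controls & library$is_negative_control)
  validate_library(library[keep, , drop = FALSE])
}

# interior wells of an edge-excluded 96-well plate: rows B-G, columns 2-11
interior_wells <- function() {
  as.vector(outer(LETTERS[2:7], 2:11, function(r, c) paste0(r, c)))
}

#' Arrange a library on edge-excluded 96-well plates
#'
#' Assigns each target gene to one interior well (rows B--G, columns 2--11;
#' the outer ring is excluded) of a multi-well plate, with
#' `controls_per_plate` wells per plate carrying the negative-control gene.
#' With the defaults, a 200-gene library yields four plates of 50 targets +
#' 10 controls. If the last plate receives fewer than `targets_per_plate`
#' targets, its spare target wells are padded with extra controls (warned).
#'
#' @param library An `ern_library` tibble.
#' @param targets_per_plate Targets per plate (default 50).
#' @param controls_per_plate Negative-control wells per plate (default 10).
#' @param seed Optional seed; well assignment is deterministic given it.
#'
#' @return A tibble with class `ern_layout` and columns `plate_id`, `well`,
#'   `gene_id`, `is_control`.
#' @export
layout_plates <- function(library, targets_per_plate = 50,
                          controls_per_plate = 10, seed = NULL) {
  library <- validate_library(library)
  if (targets_per_plate + controls_per_plate > 60) {
    abort(sprintf(
      "Infeasible layout: %d targets + %d controls exceed the 60 interior wells of an edge-excluded plate.",
      targets_per_plate, controls_per_plate
    ))
  }
  if (targets_per_plate < 1) abort("`targets_per_plate` must be >= 1.")
  ctrl <- library$gene_id[library$is_negative_control]
  if (controls_per_plate > 0 && length(ctrl) != 1) {
    abort("Library must designate exactly one negative-control gene.")
  }
  if (controls_per_plate == 0) warn("Layout has no negative-control wells; fitness normalization will be impossible.")

  targets <- library$gene_id[!library$is_negative_control]
  n_plates <- max(1L, ceiling(length(targets) / targets_per_plate))
  if (length(targets) %% targets_per_plate != 0 && length(targets) > 0) {
    warn("Targets do not fill the last plate; spare target wells padded with extra controls.")
  }

  build <- function() {
    purrr::map(seq_len(n_plates), function(p) {
      plate_targets <- targets[seq((p - 1) * targets_per_plate + 1,
                                   min(p * targets_per_plate, length(targets)))]
      n_ctrl <- controls_per_plate + (targets_per_plate - length(plate_targets))
      genes <- c(plate_targets, rep(ctrl, n_ctrl))
      wells <- sample(interior_wells(), length(genes))
      tibble(
        plate_id = sprintf("P%d", p),
        well = wells,
        gene_id = genes,
        is_control = genes %in% ctrl
      )
    }) %>% bind_rows()
  }
  out <- if (is.null(seed)) build() else with_seed(seed, build())
  out <- arrange(out, .data$plate_id, .data$well)
  class(out) <- unique(c("ern_layout", class(out)))
  out
}

# internal sanity checks shared by readers and generators
validate_layout <- function(layout) {
  stopifnot(all(c("plate_id", "well", "gene_id", "is_control") %in% names(layout)))
  if (!all(layout$well %in% interior_wells())) {
    abort("Layout assigns edge wells; only rows B-G, columns 2-11 are usable.")
  }
  tg <- layout$gene_id[!layout$is_control]
  if (anyDuplicated(tg)) abort("A target gene appears in more than one well.")
  out <- as_tibble(layout)
  class(out) <- unique(c("ern_layout", class(out)))
  out
}

validate_screen <- function(screen) {
  req <- c("plate_id", "well", "gene_id", "condition", "replicate", "cell_count")
  missing_cols <- setdiff(req, names(screen))
  if (length(missing_cols)) {
    abort(paste0("Screen table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  key <- paste(screen$plate_id, screen$well, screen$condition, screen$replicate)
  if (anyDuplicated(key)) abort("Duplicate (plate, well, condition, replicate) records in screen table.")
  if (any(screen$cell_count < 0, na.rm = TRUE)) abort("cell_count must be non-negative.")
  as_tibble(screen)
}
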