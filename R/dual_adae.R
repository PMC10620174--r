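#' Architecture of the dual adversarial deconfounding autoencoder
#'
#' The backbone is an autoencoder (default 45-32-16-32-45, rectifier
#' hidden units, linear output). Two adversarial classification heads
#' branch from the 16-dimensional embedding: one predicts the center
#' (2 classes by default), one the scanner (5 classes by default), each
#' with two 50-unit hidden layers and a linear logit output.
#'
#' @param input_dim number of radiomic features d
#' @param encoder_widths layer widths of the encoder, input first
#' @param decoder_widths layer widths of the decoder, embedding first
#' @param adversary_hidden hidden widths shared by both heads
#' @param n_center,n_scanner numbers of center / scanner classes
#' @param adversary_input input width of the heads; must equal the
#'   embedding width (the heads consume the embedding)
#' @return object of class `adae_spec`
#' @export
adae_spec <- function(input_dim = 45,
                      encoder_widths = c(input_dim, 32, 16),
                      decoder_widths = rev(encoder_widths),
                      adversary_hidden = c(50, 50),
                      n_center = 2, n_scanner = 5,
                      adversary_input = encoder_widths[length(encoder_widths)]) {
  emb <- encoder_widths[length(encoder_widths)]
  if (decoder_widths[1] != emb) {
    stopf("adae_spec error: decoder input width (%d) must equal embedding width (%d)",
          decoder_widths[1], emb)
  }
  if (adversary_input != emb) {
    stopf("adae_spec error: adversary input width (%d) must equal embedding width (%d)",
          adversary_input, emb)
  }
  if (encoder_widths[1] != input_dim || decoder_widths[length(decoder_widths)] != input_dim) {
    stopf("adae_spec error: encoder input and decoder output must both be d = %d", input_dim)
  }
  structure(list(input_dim = as.integer(input_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 adversary_hidden = as.integer(adversary_hidden),
                 n_center = as.integer(n_center),
                 n_scanner = as.integer(n_scanner)),
            class = "adae_spec")
}

#' Training configuration for the dual AD-AE
#'
#' @param lambda_center,lambda_scanner adversary weights in the encoder
#'   objective (both 1 by default)
#' @param batch_size minibatch size (default 128)
#' @param adversary_steps adversary updates per autoencoder update
#'   (default 3: a single step leaves the heads lagging behind the
#'   encoder, and an adversary that cannot find the batch signal sends
#'   no gradient to remove it)
#' @param lr,adversary_lr Adam learning rates
#' @param max_epochs epoch cap
#' @param patience early-stopping patience on the validation objective
#' @param validation_fraction lesion-level fraction held out for early
#'   stopping
#' @param monitor quantity watched for early stopping and snapshot
#'   selection. `"constrained"` (default) is the validation
#'   reconstruction MSE plus a lambda-weighted hinge penalty
#'   `max(0, H - CE)` per head, where H is the base-rate entropy of the
#'   validation labels: it selects the best-reconstructing epoch among
#'   those whose adversaries are at chance. `"reconstruction"` ignores
#'   the heads; `"objective"` is the raw minimax objective (whose
#'   minimum rewards transient adversary-loss spikes and tends to select
#'   an early, under-deconfounded encoder).
#' @param seed RNG seed for the validation split, shuffling and any
#'   stochastic choices during training
#' @return object of class `adae_config`
#' @export
adae_config <- function(lambda_center = 1, lambda_scanner = 1,
                        batch_size = 128, adversary_steps = 3,
                        lr = 1e-3, adversary_lr = 1e-3,
                        max_epochs = 2000, patience = 20,
                        validation_fraction = 0.1,
                        monitor = c("constrained", "reconstruction", "objective"),
                        seed = 1) {
  stopifnot(lambda_center >= 0, lambda_scanner >= 0, batch_size >= 1,
            adversary_steps >= 1, max_epochs >= 1, patience >= 1,
            validation_fraction > 0, validation_fraction < 1)
  monitor <- match.arg(monitor)
  structure(list(lambda_center = lambda_center, lambda_scanner = lambda_scanner,
                 batch_size = as.integer(batch_size),
                 adversary_steps = as.integer(adversary_steps),
                 lr = lr, adversary_lr = adversary_lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 monitor = monitor,
                 seed = as.integer(seed)),
            class = "adae_config")
}

#' Initialize an (untrained) dual AD-AE
#'
#' He-initialized weights, zero biases; the same seed reproduces the
#' parameters bitwise.
#'
#' @param spec an `adae_spec`
#' @param seed integer RNG seed
#' @return object of class `dual_adae`
#' @export
init_adae <- function(spec = adae_spec(), seed = 1) {
  stopifnot(inherits(spec, "adae_spec"))
  emb <- spec$encoder_widths[length(spec$encoder_widths)]
  params <- with_seed(seed, list(
    encoder = mlp_init(spec$encoder_widths),
    decoder = mlp_init(spec$decoder_widths),
    head_center = mlp_init(c(emb, spec$adversary_hidden, spec$n_center)),
    head_scanner = mlp_init(c(emb, spec$adversary_hidden, spec$n_scanner))))
  structure(list(spec = spec, params = params, history = NULL,
                 classes = NULL, config = NULL, init_seed = as.integer(seed)),
            class = "dual_adae")
}

#' @export
print.dual_adae <- function(x, ...) {
  cat(sprintf("<dual_adae> %s, %s parameters, %s\n",
              paste(x$spec$encoder_widths, collapse = "-"),
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) "untrained"
              else sprintf("trained %d epochs (best %d)",
                           nrow(x$history), attr(x$history, "best_epoch"))))
  invisible(x)
}

#' Total number of trainable parameters of a dual AD-AE
#' @param model a `dual_adae`
#' @return integer parameter count (weights + biases of encoder, decoder
#'   and both adversary heads)
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE),
             function(l) length(l$W) + length(l$b), 0))
}

adae_check_input <- function(model, table) {
  m <- feature_matrix(table)
  dimnames(m) <- NULL
  if (ncol(m) != model$spec$input_dim) {
    stopf("dual_adae shape error: model expects d = %d features, table has %d",
          model$spec$input_dim, ncol(m))
  }
  m
}

#' Encode lesions into the embedding space
#' @param model a `dual_adae`
#' @param table a `lesion_table` with matching feature dimension
#' @return n x embedding matrix with lesion ids as rownames
#' @export
adae_encode <- function(model, table) {
  x <- adae_check_input(model, table)
  h <- mlp_forward(model$params$encoder, x)
  e <- h[[length(h)]]
  rownames(e) <- table$lesion_id
  colnames(e) <- paste0("e", seq_len(ncol(e)))
  e
}

#' Reconstruct lesions through the autoencoder
#' @param model a `dual_adae`
#' @param table a `lesion_table`
#' @return list with `reconstruction` (n x d) and `mse` (mean over rows
#'   and features of the squared residual)
#' @export
adae_reconstruct <- function(model, table) {
  x <- adae_check_input(model, table)
  e <- mlp_forward(model$params$encoder, x)
  xhat <- mlp_forward(model$params$decoder, e[[length(e)]])
  xhat <- xhat[[length(xhat)]]
  dimnames(xhat) <- dimnames(x)
  list(reconstruction = xhat, mse = mean((x - xhat)^2))
}

#' Write an embedding table (ids + e1..ek columns) to CSV
#' @param model a trained `dual_adae`
#' @param table a `lesion_table`
#' @param path output CSV path
#' @export
write_embeddings <- function(model, table, path) {
  e <- adae_encode(model, table)
  df <- data.frame(lesion_id = table$lesion_id, patient_id = table$patient_id,
                   center = table$center, scanner = table$scanner,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(e))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train a dual AD-AE by alternating minimax
#'
#' Per minibatch: (a) the adversary step updates only the two heads,
#' minimizing the cross-entropy of center and scanner predictions from
#' the (frozen) embedding; (b) the autoencoder step updates only the
#' encoder and decoder, minimizing reconstruction error minus the
#' lambda-weighted adversary cross-entropies — so the encoder learns an
#' embedding the heads cannot classify. Early stopping monitors the same
#' objective on a held-out validation split and the best-validation
#' snapshot is returned. When both lambdas are zero the adversary step is
#' skipped entirely and training reduces to a plain autoencoder.
#'
#' The input table is expected on a standardized scale (see
#' [standardize()]); training on raw scales makes the reconstruction and
#' adversary terms incommensurable.
#'
#' @param model an initialized `dual_adae`
#' @param table a standardized `lesion_table`
#' @param config an `adae_config`
#' @return the trained `dual_adae`, with per-epoch `history` and the
#'   class levels used for the heads
#' @export
train_adae <- function(model, table, config = adae_config()) {
  stopifnot(inherits(model, "dual_adae"), inherits(config, "adae_config"))
  x <- adae_check_input(model, table)
  center <- factor(table$center)
  scanner <- factor(table$scanner)
  if (nlevels(center) > model$spec$n_center) {
    stopf("train error: %d center classes but head has %d outputs",
          nlevels(center), model$spec$n_center)
  }
  if (nlevels(scanner) > model$spec$n_scanner) {
    stopf("train error: %d scanner classes but head has %d outputs",
          nlevels(scanner), model$spec$n_scanner)
  }
  yc_full <- matrix(0, nrow(x), model$spec$n_center)
  yc_full[cbind(seq_len(nrow(x)), as.integer(center))] <- 1
  ys_full <- matrix(0, nrow(x), model$spec$n_scanner)
  ys_full[cbind(seq_len(nrow(x)), as.integer(scanner))] <- 1

  l1 <- config$lambda_center
  l2 <- config$lambda_scanner
  adversarial <- (l1 > 0 || l2 > 0)

  with_seed(config$seed, {
    n <- nrow(x)
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    for (lab in list(list(center, "center"), list(scanner, "scanner"))) {
      val_only <- setdiff(unique(as.integer(lab[[1]][val_idx])),
                          unique(as.integer(lab[[1]][tr_idx])))
      if (length(val_only) > 0) {
        stopf("train error: %s class '%s' present in validation but absent in training",
              lab[[2]], levels(lab[[1]])[val_only[1]])
      }
    }
    x_tr <- x[tr_idx, , drop = FALSE]; x_val <- x[val_idx, , drop = FALSE]
    yc_tr <- yc_full[tr_idx, , drop = FALSE]; yc_val <- yc_full[val_idx, , drop = FALSE]
    ys_tr <- ys_full[tr_idx, , drop = FALSE]; ys_val <- ys_full[val_idx, , drop = FALSE]
    base_entropy <- function(y) { f <- colMeans(y); f <- f[f > 0]; -sum(f * log(f)) }
    ent_center <- base_entropy(yc_val)
    ent_scanner <- base_entropy(ys_val)

    p <- model$params
    opt <- list(encoder = adam_init(p$encoder), decoder = adam_init(p$decoder),
                head_center = adam_init(p$head_center),
                head_scanner = adam_init(p$head_scanner))

    evaluate <- function(pp, xs, yc, ys) {
      he <- mlp_forward(pp$encoder, xs)
      e <- he[[length(he)]]
      hd <- mlp_forward(pp$decoder, e)
      rec <- mean((xs - hd[[length(hd)]])^2)
      ce1 <- softmax_ce(nn_last(mlp_forward(pp$head_center, e)), yc)$loss
      ce2 <- softmax_ce(nn_last(mlp_forward(pp$head_scanner, e)), ys)$loss
      c(rec = rec, ce_center = ce1, ce_scanner = ce2,
        objective = rec - l1 * ce1 - l2 * ce2)
    }

    n_tr <- nrow(x_tr)
    n_batches <- max(1L, floor(n_tr / config$batch_size))
    hist <- list()
    best <- list(objective = Inf, params = p, epoch = 0L)
    wait <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n_tr)
      for (bi in seq_len(n_batches)) {
        rows <- perm[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n_tr)]
        xb <- x_tr[rows, , drop = FALSE]
        ycb <- yc_tr[rows, , drop = FALSE]
        ysb <- ys_tr[rows, , drop = FALSE]

        if (adversarial) {
          for (s in seq_len(config$adversary_steps)) {
            he <- mlp_forward(p$encoder, xb)
            e <- he[[length(he)]]
            h1 <- mlp_forward(p$head_center, e)
            g1 <- softmax_ce(nn_last(h1), ycb)
            b1 <- mlp_backward(p$head_center, h1, g1$grad)
            u <- adam_step(p$head_center, b1$grads, opt$head_center, config$adversary_lr)
            p$head_center <- u$layers; opt$head_center <- u$state
            h2 <- mlp_forward(p$head_scanner, e)
            g2 <- softmax_ce(nn_last(h2), ysb)
            b2 <- mlp_backward(p$head_scanner, h2, g2$grad)
            u <- adam_step(p$head_scanner, b2$grads, opt$head_scanner, config$adversary_lr)
            p$head_scanner <- u$layers; opt$head_scanner <- u$state
          }
        }

        # autoencoder step: reconstruction minus lambda-weighted adversary
        # losses; gradients flow through the (frozen) heads into the encoder
        he <- mlp_forward(p$encoder, xb)
        e <- he[[length(he)]]
        hd <- mlp_forward(p$decoder, e)
        xhat <- hd[[length(hd)]]
        d_rec <- 2 * (xhat - xb) / length(xb)
        bd <- mlp_backward(p$decoder, hd, d_rec)
        d_emb <- bd$d_input
        if (adversarial) {
          if (l1 > 0) {
            h1 <- mlp_forward(p$head_center, e)
            g1 <- softmax_ce(nn_last(h1), ycb)
            d_emb <- d_emb - l1 * mlp_backward(p$head_center, h1, g1$grad)$d_input
          }
          if (l2 > 0) {
            h2 <- mlp_forward(p$head_scanner, e)
            g2 <- softmax_ce(nn_last(h2), ysb)
            d_emb <- d_emb - l2 * mlp_backward(p$head_scanner, h2, g2$grad)$d_input
          }
        }
        be <- mlp_backward(p$encoder, he, d_emb)
        u <- adam_step(p$decoder, bd$grads, opt$decoder, config$lr)
        p$decoder <- u$layers; opt$decoder <- u$state
        u <- adam_step(p$encoder, be$grads, opt$encoder, config$lr)
        p$encoder <- u$layers; opt$encoder <- u$state
      }

      tr_m <- evaluate(p, x_tr, yc_tr, ys_tr)
      val_m <- evaluate(p, x_val, yc_val, ys_val)
      if (!all(is.finite(c(tr_m, val_m)))) {
        stopf("train divergence error: non-finite loss at epoch %d", epoch)
      }
      crit <- switch(config$monitor,
        reconstruction = val_m[["rec"]],
        objective = val_m[["objective"]],
        constrained = val_m[["rec"]] +
          l1 * max(0, ent_center - val_m[["ce_center"]]) +
          l2 * max(0, ent_scanner - val_m[["ce_scanner"]]))
      hist[[epoch]] <- c(epoch = epoch, train = tr_m, val = val_m,
                         val.criterion = crit)
      if (crit < best$objective - 1e-6) {
        best <- list(objective = crit, params = p, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }

    history <- as.data.frame(do.call(rbind, hist))
    attr(history, "best_epoch") <- best$epoch
    model$params <- best$params
    model$history <- history
    model$classes <- list(center = levels(center), scanner = levels(scanner))
    model$config <- config
    model
  })
}

# flatten/restore parameter lists for the JSON checkpoint
params_to_list <- function(layers) {
  lapply(layers, function(l) list(W = list(dim = dim(l$W), data = as.numeric(l$W)),
                                  b = as.numeric(l$b)))
}

params_from_list <- function(x) {
  lapply(x, function(l) list(
    W = matrix(unlist(l$W$data), l$W$dim[1], l$W$dim[2]),
    b = as.numeric(unlist(l$b))))
}

#' Save / load a dual AD-AE checkpoint
#'
#' A single portable JSON file holding the architecture, training
#' configuration, all parameters and the training history. Doubles are
#' written at full precision, so a save/load round trip reproduces the
#' parameters bit-exactly.
#'
#' @param model a `dual_adae`
#' @param path checkpoint path
#' @export
save_adae <- function(model, path) {
  obj <- list(
    spec = unclass(model$spec),
    config = if (is.null(model$config)) NULL else unclass(model$config),
    init_seed = model$init_seed,
    classes = model$classes,
    params = lapply(model$params, params_to_list),
    history = model$history,
    best_epoch = if (is.null(model$history)) NULL else attr(model$history, "best_epoch"))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname save_adae
#' @return `load_adae` returns the restored `dual_adae`
#' @export
load_adae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spec <- do.call(adae_spec, obj$spec[c("input_dim", "encoder_widths",
                                        "decoder_widths", "adversary_hidden",
                                        "n_center", "n_scanner")])
  model <- structure(list(
    spec = spec,
    params = lapply(obj$params, params_from_list),
    history = obj$history,
    classes = obj$classes,
    config = if (is.null(obj$config)) NULL else do.call(adae_config, obj$config),
    init_seed = obj$init_seed), class = "dual_adae")
  if (!is.null(model$history)) {
    model$history <- as.data.frame(model$history)
    attr(model$history, "best_epoch") <- obj$best_epoch
  }
  model
}
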