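#' Assemble the SM--miRNA heterogeneous graph
#'
#' Joins the denoised association matrix with the two integrated
#' similarity matrices into one `(nm + ns)` node graph, miRNA block
#' first.  The similarity blocks are first symmetrically degree
#' normalized (`D^{-1/2} S D^{-1/2}`); the input graph `G` additionally
#' scales those diagonal blocks by the penalty factor `mu`, which tilts
#' message passing toward within-type similarity edges.  The initial
#' embedding matrix `H0` carries only the cross-type association blocks.
#'
#' @param A_star real-valued association matrix, `ns` SMs x `nm` miRNAs
#'   (typically the `A_star` of [denoise_associations()]).
#' @param SSM `ns x ns` SM similarity matrix.
#' @param SMR `nm x nm` miRNA similarity matrix.
#' @param mu positive penalty factor on the similarity blocks of `G`
#'   (default 6).
#' @return list of class `smma_graph`: `AH` (block adjacency without the
#'   penalty), `G` (penalized input graph), `H0`, `d` (degree vector of
#'   `G`), `Ghat` (`D^{-1/2} G D^{-1/2}`), `nm`, `ns`.  Zero-degree
#'   nodes get all-zero normalized rows/columns with a warning rather
#'   than NaNs.
#' @export
build_hetero_graph <- function(A_star, SSM, SMR, mu = 6) {
  A_star <- as.matrix(A_star)
  ns <- nrow(A_star); nm <- ncol(A_star)
  if (!all(dim(SSM) == ns)) stop("SSM must be ", ns, "x", ns)
  if (!all(dim(SMR) == nm)) stop("SMR must be ", nm, "x", nm)
  stopifnot(mu > 0)
  SSMn <- sym_degree_norm(SSM, "SM similarity")
  SMRn <- sym_degree_norm(SMR, "miRNA similarity")
  blocks <- function(scale) rbind(cbind(scale * SMRn, t(A_star)),
                                  cbind(A_star, scale * SSMn))
  AH <- blocks(1)
  G <- blocks(mu)
  H0 <- rbind(cbind(matrix(0, nm, nm), t(A_star)),
              cbind(A_star, matrix(0, ns, ns)))
  d <- rowSums(G)
  structure(list(AH = AH, G = G, H0 = H0, d = d,
                 Ghat = sym_degree_norm(G, "input graph", warn = FALSE),
                 nm = nm, ns = ns),
            class = "smma_graph")
}

# D^{-1/2} S D^{-1/2} with zero-degree rows/columns mapped to zero
sym_degree_norm <- function(S, what = "matrix", warn = TRUE) {
  d <- rowSums(S)
  zero <- d <= 0
  if (any(zero) && warn)
    warning(sum(zero), " zero-degree node(s) in ", what,
            "; normalized rows/columns set to 0")
  inv <- ifelse(zero, 0, 1 / sqrt(d))
  S * outer(inv, inv)
}

#' Initialize the layer-attention GCN model
#'
#' Weight matrices use symmetric-uniform (Glorot) fan-based
#' initialization; the first layer maps the `(nm+ns)`-dimensional input
#' to `k` dimensions, later layers are `k x k`.  Layer attention
#' coefficients start at `1/(l+1)` for layer `l = 1..L` and are trained
#' freely (no softmax constraint).
#'
#' @param nm,ns numbers of miRNAs and SMs.
#' @param cfg a [run_config()].
#' @return list of class `smma_gcn`: `W` (list of `L` weight matrices),
#'   `a` (attention scalars), `W_dec` (`k x k` decoder matrix), `nm`,
#'   `ns`, `k`, `L`, dropout rates.  Uses the current RNG state.
#' @export
init_gcn_model <- function(nm, ns, cfg = run_config()) {
  k <- cfg$embed_dim; L <- cfg$n_layers
  n <- nm + ns
  glorot <- function(fin, fout) {
    s <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -s, s), fin, fout)
  }
  W <- vector("list", L)
  W[[1]] <- glorot(n, k)
  if (L > 1) for (l in 2:L) W[[l]] <- glorot(k, k)
  structure(list(W = W, a = 1 / (seq_len(L) + 1), W_dec = glorot(k, k),
                 nm = nm, ns = ns, k = k, L = L,
                 dropout_edge = cfg$dropout_edge,
                 dropout_feature = cfg$dropout_feature),
            class = "smma_gcn")
}

elu <- function(z) ifelse(z > 0, z, exp(z) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(z))

# inverted dropout mask: entries are 0 or 1/(1-p)
dropout_mask <- function(nr, nc, p) {
  matrix(ifelse(stats::runif(nr * nc) < p, 0, 1 / (1 - p)), nr, nc)
}

# Forward pass keeping every intermediate needed for backprop.
gcn_forward_internal <- function(graph, model, training = FALSE) {
  L <- model$L
  Ghat <- graph$Ghat
  if (training && model$dropout_edge > 0)
    Ghat <- Ghat * dropout_mask(nrow(Ghat), ncol(Ghat), model$dropout_edge)
  H <- vector("list", L + 1)     # H[[l+1]] = embeddings after layer l
  Z <- MF <- Fm <- vector("list", L)
  mask <- vector("list", L)
  H[[1]] <- graph$H0
  for (l in seq_len(L)) {
    Fl <- H[[l]]
    if (training && model$dropout_feature > 0) {
      mask[[l]] <- dropout_mask(nrow(Fl), ncol(Fl), model$dropout_feature)
      Fl <- Fl * mask[[l]]
    }
    Fm[[l]] <- Fl
    MF[[l]] <- Ghat %*% Fl
    Z[[l]] <- MF[[l]] %*% model$W[[l]]
    if (!all(is.finite(Z[[l]])))
      stop("non-finite values in GCN layer ", l)
    H[[l + 1]] <- elu(Z[[l]])
  }
  list(H = H[-1], Z = Z, MF = MF, Fmask = mask, Ghat = Ghat)
}

#' Run the graph convolution encoder
#'
#' Applies `H(l+1) = ELU(D^{-1/2} G D^{-1/2} H(l) W(l))` for `L` layers
#' starting from the association-only embedding `H0`.  With
#' `training = TRUE`, dropout is applied to the normalized adjacency
#' (one mask per forward pass) and to each layer's input features; with
#' `training = FALSE` the pass is deterministic.
#'
#' @param graph a [build_hetero_graph()] result.
#' @param model an [init_gcn_model()] result.
#' @param training logical; enables dropout (draws from the current
#'   RNG).
#' @return list of `L` embedding matrices, each `(nm+ns) x k`.
#' @export
gcn_forward <- function(graph, model, training = FALSE) {
  gcn_forward_internal(graph, model, training)$H
}

#' Combine layer embeddings with attention weights
#'
#' The final embedding is the attention-weighted sum over layers,
#' `sum_l a_l H(l)`; its first `nm` rows are the miRNA embeddings and
#' the remaining `ns` rows the SM embeddings.
#'
#' @param H_list list of same-shaped layer embedding matrices.
#' @param a numeric attention coefficients, one per layer.
#' @param nm number of miRNA rows.
#' @return list with `Hm` (`nm x k`) and `Hs` (`ns x k`).
#' @export
attention_combine <- function(H_list, a, nm) {
  if (length(a) != length(H_list))
    stop("need one attention coefficient per layer")
  H <- a[1] * H_list[[1]]
  if (length(a) > 1)
    for (l in 2:length(a)) H <- H + a[l] * H_list[[l]]
  list(Hm = H[seq_len(nm), , drop = FALSE],
       Hs = H[-seq_len(nm), , drop = FALSE])
}

#' Decode embeddings into association scores
#'
#' Bilinear decoder `A' = sigmoid(Hm W' Hs^T)`: entry `(i, j)` is the
#' predicted association score between miRNA `i` and SM `j`, strictly
#' inside (0, 1).
#'
#' @param Hm miRNA embeddings (`nm x k`).
#' @param Hs SM embeddings (`ns x k`).
#' @param W_dec trainable `k x k` decoder matrix.
#' @return `nm x ns` score matrix.
#' @export
decode <- function(Hm, Hs, W_dec) {
  p <- stats::plogis(Hm %*% W_dec %*% t(Hs))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

# weighted binary cross-entropy; Y and P are nm x ns, w is the positive
# class weight
wbce_loss <- function(P, Y, w) {
  -mean(w * Y * log(P) + (1 - Y) * log(1 - P))
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the full denoise-embed-score pipeline
#'
#' End-to-end fit: the binary association matrix is denoised by
#' [denoise_associations()], the heterogeneous graph is assembled by
#' [build_hetero_graph()], and the layer-attention GCN is trained for
#' `cfg$epochs` full-matrix Adam steps against the original binary
#' associations.  The loss is binary cross-entropy over every SM-miRNA
#' cell, with known associations up-weighted by the negative/positive
#' count ratio (`loss = "weighted_bce"`, the default) to counter the
#' extreme class imbalance of curated association data.  All weight
#' initialization and dropout randomness derives from `cfg$seed`, so a
#' repeated call reproduces the fit exactly.
#'
#' @param data an [association_data()] object (the binary training
#'   associations).
#' @param SSM integrated SM similarity (`ns x ns`).
#' @param SMR integrated miRNA similarity (`nm x nm`).
#' @param cfg a [run_config()].
#' @return list of class `smma_fit`: `A_prime` (`nm x ns` score matrix
#'   from the final dropout-free forward pass, miRNA rows), `model`,
#'   `graph`, `denoised` (the LRR result), `loss_history` (length
#'   `epochs`), and `cfg`.
#' @export
train_model <- function(data, SSM, SMR, cfg = run_config()) {
  stopifnot(inherits(data, "smma_association"))
  validate_config(cfg)
  set.seed(cfg$seed)
  den <- denoise_associations(data, ialm_config(alpha = cfg$lrr_alpha),
                              side = cfg$lrr_side)
  graph <- build_hetero_graph(den$A_star, SSM, SMR, cfg$graph_penalty)
  model <- init_gcn_model(graph$nm, graph$ns, cfg)
  Y <- t(data$A)                       # nm x ns, matching the decoder
  npos <- sum(Y)
  w <- if (cfg$loss == "weighted_bce" && npos > 0)
    (length(Y) - npos) / npos else 1
  L <- model$L
  params <- c(model$W, list(a = model$a, W_dec = model$W_dec))
  st <- adam_state(params)
  nm <- graph$nm
  N <- length(Y)
  loss_history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fw <- gcn_forward_internal(graph, model, training = TRUE)
    emb <- attention_combine(fw$H, model$a, nm)
    P <- decode(emb$Hm, emb$Hs, model$W_dec)
    loss <- wbce_loss(P, Y, w)
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
    loss_history[ep] <- loss

    # backward
    dS <- (w * Y * (P - 1) + (1 - Y) * P) / N        # nm x ns
    gW_dec <- crossprod(emb$Hm, dS %*% emb$Hs)
    dHm <- dS %*% emb$Hs %*% t(model$W_dec)
    dHs <- crossprod(dS, emb$Hm %*% model$W_dec)
    dHfin <- rbind(dHm, dHs)
    ga <- vapply(fw$H, function(Hl) sum(dHfin * Hl), 0)
    gW <- vector("list", L)
    dH <- model$a[L] * dHfin
    for (l in L:1) {
      dZ <- dH * elu_grad(fw$Z[[l]])
      gW[[l]] <- crossprod(fw$MF[[l]], dZ)
      if (l > 1) {
        dF <- crossprod(fw$Ghat, dZ %*% t(model$W[[l]]))
        if (!is.null(fw$Fmask[[l]])) dF <- dF * fw$Fmask[[l]]
        dH <- model$a[l - 1] * dHfin + dF
      }
    }

    grads <- c(gW, list(a = ga, W_dec = gW_dec))
    for (j in seq_along(params)) {
      upd <- adam_step(params[[j]], grads[[j]], st[[j]],
                       cfg$learning_rate, ep)
      params[[j]] <- upd$p
      st[[j]] <- upd$st
    }
    model$W <- params[seq_len(L)]
    model$a <- params$a
    model$W_dec <- params$W_dec
  }
  H <- gcn_forward(graph, model, training = FALSE)
  emb <- attention_combine(H, model$a, nm)
  A_prime <- decode(emb$Hm, emb$Hs, model$W_dec)
  dimnames(A_prime) <- list(data$mirna_ids, data$sm_ids)
  structure(list(A_prime = A_prime, model = model, graph = graph,
                 denoised = den, loss_history = loss_history, cfg = cfg),
            class = "smma_fit")
}

#' Extract scores in association orientation
#'
#' Transposes the `nm x ns` decoder output of an `smma_fit` into the
#' `ns x nm` orientation of the association matrix (SM rows), which the
#' evaluation and reporting functions use.
#'
#' @param fit an `smma_fit` from [train_model()].
#' @return `ns x nm` numeric score matrix.
#' @export
score_matrix <- function(fit) {
  stopifnot(inherits(fit, "smma_fit"))
  t(fit$A_prime)
}
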