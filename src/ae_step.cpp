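// One optimizer step of the CDR3 autoencoder: forward pass with dropout,
// per-block softmax output, reconstruction MSE (+ optional pairwise
// distance-preservation loss on the embedding), backpropagation, and a
// fused in-place Adam update on the flat parameter vector.
//
// The flat parameter vector `theta` and the Adam moments `mAd`/`vAd` are
// modified in place; they are owned exclusively by the R training loop.
// Weight matrices are Armadillo views into `theta`'s memory (no copies),
// laid out as W1,b1,...,W6,b6 with column-major matrices, mirroring how
// the R side unlists them. Dropout masks consume R's RNG stream
// (column-major, layer by layer), so runs are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void eluInplace(arma::mat& A) {
    for (arma::uword i = 0; i < A.n_elem; ++i)
        if (A[i] < 0) A[i] = std::expm1(A[i]);
}

// derivative of Elu from the *post-activation* value: 1 if h > 0 else h + 1
static inline arma::mat dEluFromAct(const arma::mat& H) {
    arma::mat D(H.n_rows, H.n_cols);
    for (arma::uword i = 0; i < H.n_elem; ++i)
        D[i] = H[i] > 0 ? 1.0 : H[i] + 1.0;
    return D;
}

static inline arma::mat dropoutMask(arma::uword r, arma::uword c, double p) {
    arma::mat M(r, c);
    const double scale = 1.0 / (1.0 - p);
    for (arma::uword i = 0; i < M.n_elem; ++i)  // column-major, R order
        M[i] = (unif_rand() >= p) ? scale : 0.0;
    return M;
}

// softmax over column range [s, s+w) of each row, in place
static inline void blockSoftmax(arma::mat& A, arma::uword s, arma::uword w) {
    for (arma::uword i = 0; i < A.n_rows; ++i) {
        double mx = A(i, s);
        for (arma::uword j = 1; j < w; ++j) mx = std::max(mx, A(i, s + j));
        double tot = 0.0;
        for (arma::uword j = 0; j < w; ++j) {
            double e = std::exp(A(i, s + j) - mx);
            A(i, s + j) = e;
            tot += e;
        }
        for (arma::uword j = 0; j < w; ++j) A(i, s + j) /= tot;
    }
}

// gradient through one softmax block: dA = S .* (dY - rowSums(dY .* S))
static inline void blockSoftmaxBackward(arma::mat& dA, const arma::mat& dY,
                                        const arma::mat& S,
                                        arma::uword s, arma::uword w) {
    for (arma::uword i = 0; i < dA.n_rows; ++i) {
        double dot = 0.0;
        for (arma::uword j = 0; j < w; ++j)
            dot += dY(i, s + j) * S(i, s + j);
        for (arma::uword j = 0; j < w; ++j)
            dA(i, s + j) = S(i, s + j) * (dY(i, s + j) - dot);
    }
}

static arma::mat pdist(const arma::mat& X) {
    arma::vec sq = arma::sum(arma::square(X), 1);
    arma::mat D2 = arma::repmat(sq, 1, X.n_rows) +
        arma::repmat(sq.t(), X.n_rows, 1) - 2.0 * (X * X.t());
    D2.elem(arma::find(D2 < 0)).zeros();
    return arma::sqrt(D2);
}

// [[Rcpp::export]]
NumericVector cpp_ae_step(const arma::mat& Xb, NumericVector theta,
                          NumericVector mAd, NumericVector vAd,
                          IntegerVector dims, int nBlocks, int nV,
                          double p, double lr, double corr, double beta1,
                          double beta2, double eps, double lam,
                          bool useDis, bool squaredDis, bool vInDist) {
    const arma::uword b = Xb.n_rows, n = Xb.n_cols;
    const arma::uword d1 = dims[1], d2 = dims[2], d3 = dims[3];
    if ((arma::uword)dims[0] != n) stop("input width mismatch");

    double* tp = REAL(theta);
    R_xlen_t off = 0;
    auto matView = [&](arma::uword r, arma::uword c) {
        arma::mat M(tp + off, r, c, false, true);
        off += (R_xlen_t)r * c;
        return M;
    };
    auto vecView = [&](arma::uword L) {
        arma::rowvec v(tp + off, L, false, true);
        off += L;
        return v;
    };
    arma::mat W1 = matView(n, d1);  arma::rowvec b1 = vecView(d1);
    arma::mat W2 = matView(d1, d2); arma::rowvec b2 = vecView(d2);
    arma::mat W3 = matView(d2, d3); arma::rowvec b3 = vecView(d3);
    arma::mat W4 = matView(d3, d2); arma::rowvec b4 = vecView(d2);
    arma::mat W5 = matView(d2, d1); arma::rowvec b5 = vecView(d1);
    arma::mat W6 = matView(d1, n);  arma::rowvec b6 = vecView(n);
    arma::mat W7 = matView(21, 21); arma::rowvec b7 = vecView(21);
    arma::mat W8;
    arma::rowvec b8;
    if (nV > 0) { W8 = matView(nV, nV); b8 = vecView(nV); }
    if (off != theta.size()) stop("parameter vector size mismatch");

    // ---- forward with dropout ----
    arma::mat H1 = Xb * W1; H1.each_row() += b1; eluInplace(H1);
    arma::mat M1 = dropoutMask(b, d1, p); arma::mat H1d = H1 % M1;
    arma::mat H2 = H1d * W2; H2.each_row() += b2; eluInplace(H2);
    arma::mat M2 = dropoutMask(b, d2, p); arma::mat H2d = H2 % M2;
    arma::mat Z = H2d * W3; Z.each_row() += b3; eluInplace(Z);
    arma::mat M3 = dropoutMask(b, d3, p); arma::mat Zd = Z % M3;
    arma::mat H4 = Zd * W4; H4.each_row() += b4; eluInplace(H4);
    arma::mat M4 = dropoutMask(b, d2, p); arma::mat H4d = H4 % M4;
    arma::mat H5 = H4d * W5; H5.each_row() += b5; eluInplace(H5);
    arma::mat M5 = dropoutMask(b, d1, p); arma::mat H5d = H5 % M5;
    arma::mat A6 = H5d * W6; A6.each_row() += b6;
    // trainable output layer shared across the 21-wide position rows
    // (separate layer for the V block), softmax per row
    arma::mat Y(b, n);
    for (int blk = 0; blk < nBlocks; ++blk) {
        const arma::uword s = (arma::uword)blk * 21;
        arma::mat sub = A6.cols(s, s + 20) * W7;
        sub.each_row() += b7;
        Y.cols(s, s + 20) = sub;
        blockSoftmax(Y, s, 21);
    }
    if (nV > 0) {
        const arma::uword s = (arma::uword)nBlocks * 21;
        arma::mat sub = A6.cols(s, s + nV - 1) * W8;
        sub.each_row() += b8;
        Y.cols(s, s + nV - 1) = sub;
        blockSoftmax(Y, s, nV);
    }

    const double mse = arma::accu(arma::square(Xb - Y)) / (double)(b * n);

    // ---- distance loss on the pre-dropout embedding ----
    double dis = 0.0;
    arma::mat dZdis;
    if (useDis && b >= 2) {
        arma::mat Db = vInDist ? pdist(Xb)
                               : pdist(Xb.cols(0, n - nV - 1));
        arma::mat dz = pdist(Z);
        const double np = (double)b * (b - 1) / 2.0;
        arma::mat G(b, b);
        if (squaredDis) {
            arma::mat diff = arma::square(dz) - Db;
            dis = arma::accu(arma::square(arma::trimatu(diff, 1))) / np;
            G = (4.0 / np) * diff;
        } else {
            arma::mat diff = dz - Db;
            dis = arma::accu(arma::square(arma::trimatu(diff, 1))) / np;
            arma::mat den = dz;
            den.elem(arma::find(dz == 0)).ones();   // avoid 0/0; zeroed below
            G = (2.0 / np) * diff / den;
            G.elem(arma::find(dz == 0)).zeros();
        }
        G.diag().zeros();
        dZdis = lam * (Z.each_col() % arma::sum(G, 1) - G * Z);
    }

    // ---- backward ----
    arma::mat dY = (2.0 / (double)(b * n)) * (Y - Xb);
    arma::mat dA7(b, n);   // gradient at the shared output layer's input
    for (int blk = 0; blk < nBlocks; ++blk)
        blockSoftmaxBackward(dA7, dY, Y, (arma::uword)blk * 21, 21);
    if (nV > 0) blockSoftmaxBackward(dA7, dY, Y, (arma::uword)nBlocks * 21,
                                     nV);

    NumericVector gvecR(theta.size());
    double* gp = REAL(gvecR);
    R_xlen_t goff = 0;
    auto gMat = [&](arma::uword r, arma::uword c) {
        arma::mat M(gp + goff, r, c, false, true);
        goff += (R_xlen_t)r * c;
        return M;
    };
    auto gVec = [&](arma::uword L) {
        arma::rowvec v(gp + goff, L, false, true);
        goff += L;
        return v;
    };
    arma::mat gW1 = gMat(n, d1);  arma::rowvec gb1 = gVec(d1);
    arma::mat gW2 = gMat(d1, d2); arma::rowvec gb2 = gVec(d2);
    arma::mat gW3 = gMat(d2, d3); arma::rowvec gb3 = gVec(d3);
    arma::mat gW4 = gMat(d3, d2); arma::rowvec gb4 = gVec(d2);
    arma::mat gW5 = gMat(d2, d1); arma::rowvec gb5 = gVec(d1);
    arma::mat gW6 = gMat(d1, n);  arma::rowvec gb6 = gVec(n);
    arma::mat gW7 = gMat(21, 21); arma::rowvec gb7 = gVec(21);

    // through the shared output layer: accumulate over position rows
    arma::mat dA6(b, n);
    gW7.zeros(); gb7.zeros();
    for (int blk = 0; blk < nBlocks; ++blk) {
        const arma::uword s = (arma::uword)blk * 21;
        const arma::mat sub6 = A6.cols(s, s + 20);
        const arma::mat dsub7 = dA7.cols(s, s + 20);
        gW7 += sub6.t() * dsub7;
        gb7 += arma::sum(dsub7, 0);
        dA6.cols(s, s + 20) = dsub7 * W7.t();
    }
    if (nV > 0) {
        arma::mat gW8 = gMat(nV, nV); arma::rowvec gb8 = gVec(nV);
        const arma::uword s = (arma::uword)nBlocks * 21;
        const arma::mat sub6 = A6.cols(s, s + nV - 1);
        const arma::mat dsub7 = dA7.cols(s, s + nV - 1);
        gW8 = sub6.t() * dsub7;
        gb8 = arma::sum(dsub7, 0);
        dA6.cols(s, s + nV - 1) = dsub7 * W8.t();
    }
    if (goff != theta.size()) stop("gradient vector size mismatch");

    gW6 = H5d.t() * dA6;                 gb6 = arma::sum(dA6, 0);
    arma::mat dA5 = (dA6 * W6.t()) % M5 % dEluFromAct(H5);
    gW5 = H4d.t() * dA5;                 gb5 = arma::sum(dA5, 0);
    arma::mat dA4 = (dA5 * W5.t()) % M4 % dEluFromAct(H4);
    gW4 = Zd.t() * dA4;                  gb4 = arma::sum(dA4, 0);
    arma::mat dZ = (dA4 * W4.t()) % M3;
    if (useDis && b >= 2) dZ += dZdis;
    arma::mat dA3 = dZ % dEluFromAct(Z);
    gW3 = H2d.t() * dA3;                 gb3 = arma::sum(dA3, 0);
    arma::mat dA2 = (dA3 * W3.t()) % M2 % dEluFromAct(H2);
    gW2 = H1d.t() * dA2;                 gb2 = arma::sum(dA2, 0);
    arma::mat dA1 = (dA2 * W2.t()) % M1 % dEluFromAct(H1);
    gW1 = Xb.t() * dA1;                  gb1 = arma::sum(dA1, 0);

    // ---- fused Adam update, in place ----
    const R_xlen_t P = theta.size();
    double *mm = REAL(mAd), *vv = REAL(vAd);
    const double lc = lr * corr, om1 = 1.0 - beta1, om2 = 1.0 - beta2;
    for (R_xlen_t i = 0; i < P; ++i) {
        const double g = gp[i];
        mm[i] = beta1 * mm[i] + om1 * g;
        vv[i] = beta2 * vv[i] + om2 * g * g;
        tp[i] -= lc * mm[i] / (std::sqrt(vv[i]) + eps);
    }

    return NumericVector::create(mse, dis);
}
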