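#pragma once

#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

// Minimal static kd-tree over 3-D points. Points are supplied column-major
// (R matrix layout: pts[i + n*dim]). Nearest-neighbour ties are broken by
// point index so results do not depend on build traversal order.
class KDTree3 {
public:
    KDTree3(const double* pts, int n, int bucket = 16)
        : pts_(pts), n_(n), bucket_(bucket), idx_(n) {
        for (int i = 0; i < n; ++i) idx_[i] = i;
        nodes_.reserve(n > 0 ? (4 * n) / bucket_ + 4 : 4);
        if (n > 0) root_ = build(0, n);
    }

    struct Hit {
        double d2;
        int idx;
    };

    // k nearest neighbours of q (array of 3 doubles); results sorted by
    // (distance, index) ascending. k is clamped to n.
    void knn(const double* q, int k, std::vector<Hit>& out) const {
        out.clear();
        if (n_ == 0) return;
        if (k > n_) k = n_;
        heap_.clear();
        k_ = k;
        search(root_, q);
        out.assign(heap_.begin(), heap_.end());
        std::sort(out.begin(), out.end(), [](const Hit& a, const Hit& b) {
            if (a.d2 != b.d2) return a.d2 < b.d2;
            return a.idx < b.idx;
        });
    }

private:
    struct Node {
        int left = -1, right = -1;   // children, -1 for leaf
        int start = 0, count = 0;    // leaf range into idx_
        int dim = 0;
        double split = 0.0;
        double lo[3], hi[3];         // bounding box
    };

    const double* pts_;
    int n_, bucket_;
    std::vector<int> idx_;
    std::vector<Node> nodes_;
    int root_ = -1;

    mutable std::vector<Hit> heap_;  // max-heap on (d2, idx)
    mutable int k_ = 0;

    double coord(int i, int d) const { return pts_[i + static_cast<std::int64_t>(n_) * d]; }

    static bool worse(const Hit& a, const Hit& b) {
        // a "less" than b in heap order <=> b is worse (larger d2, then larger idx)
        if (a.d2 != b.d2) return a.d2 < b.d2;
        return a.idx < b.idx;
    }

    int build(int start, int count) {
        int id = static_cast<int>(nodes_.size());
        nodes_.push_back(Node());
        Node& nd = nodes_[id];
        nd.start = start;
        nd.count = count;
        for (int d = 0; d < 3; ++d) {
            nd.lo[d] = std::numeric_limits<double>::infinity();
            nd.hi[d] = -std::numeric_limits<double>::infinity();
        }
        for (int i = start; i < start + count; ++i) {
            for (int d = 0; d < 3; ++d) {
                double v = coord(idx_[i], d);
                if (v < nd.lo[d]) nd.lo[d] = v;
                if (v > nd.hi[d]) nd.hi[d] = v;
            }
        }
        if (count <= bucket_) return id;
        int dim = 0;
        double ext = nd.hi[0] - nd.lo[0];
        for (int d = 1; d < 3; ++d) {
            double e = nd.hi[d] - nd.lo[d];
            if (e > ext) { ext = e; dim = d; }
        }
        if (!(ext > 0.0)) return id;  // all points coincident: keep as leaf
        int mid = start + count / 2;
        std::nth_element(idx_.begin() + start, idx_.begin() + mid,
                         idx_.begin() + start + count,
                         [&](int a, int b) {
                             double ca = coord(a, dim), cb = coord(b, dim);
                             if (ca != cb) return ca < cb;
                             return a < b;
                         });
        double split = coord(idx_[mid], dim);
        int dim_cp = dim;
        double split_cp = split;
        int left = build(start, mid - start);
        int right = build(mid, start + count - mid);
        Node& nd2 = nodes_[id];  // re-reference: vector may have reallocated
        nd2.dim = dim_cp;
        nd2.split = split_cp;
        nd2.left = left;
        nd2.right = right;
        return id;
    }

    double box_dist2(const Node& nd, const double* q) const {
        double s = 0.0;
        for (int d = 0; d < 3; ++d) {
            double v = 0.0;
            if (q[d] < nd.lo[d]) v = nd.lo[d] - q[d];
            else if (q[d] > nd.hi[d]) v = q[d] - nd.hi[d];
            s += v * v;
        }
        return s;
    }

    void offer(double d2, int i) const {
        if (static_cast<int>(heap_.size()) < k_) {
            heap_.push_back({d2, i});
            std::push_heap(heap_.begin(), heap_.end(), worse);
        } else {
            const Hit& top = heap_.front();
            Hit cand{d2, i};
            if (worse(cand, top)) {
                std::pop_heap(heap_.begin(), heap_.end(), worse);
                heap_.back() = cand;
                std::push_heap(heap_.begin(), heap_.end(), worse);
            }
        }
    }

    bool prune(const Node& nd, const double* q) const {
        if (static_cast<int>(heap_.size()) < k_) return false;
        return box_dist2(nd, q) > heap_.front().d2;
    }

    void search(int id, const double* q) const {
        const Node& nd = nodes_[id];
        if (nd.left < 0) {
            for (int i = nd.start; i < nd.start + nd.count; ++i) {
                int pi = idx_[i];
                double dx = coord(pi, 0) - q[0];
                double dy = coord(pi, 1) - q[1];
                double dz = coord(pi, 2) - q[2];
                offer(dx * dx + dy * dy + dz * dz, pi);
            }
            return;
        }
        int first = nd.left, second = nd.right;
        if (q[nd.dim] > nd.split) std::swap(first, second);
        if (!prune(nodes_[first], q)) search(first, q);
        if (!prune(nodes_[second], q)) search(second, q);
    }
};
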