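"""Line-oriented JSON worker exposing the RDKit primitives used by the R side.

Protocol: one JSON object per line on stdin -> one JSON object per line on
stdout. Every response carries "ok"; failures carry "error". The process is
stateless apart from a small cache of parsed reactions/patterns.
"""
import sys
import json

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdChemReactions
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

_rxn_cache = {}
_pat_cache = {}


def _mol(smiles, sanitize=True):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles, sanitize=sanitize)


def _canon(smiles):
    m = _mol(smiles)
    if m is None:
        return None
    return Chem.MolToSmiles(m)


def _rxn(smirks):
    r = _rxn_cache.get(smirks)
    if r is None:
        r = rdChemReactions.ReactionFromSmarts(smirks)
        if r is not None:
            r.Initialize()
        _rxn_cache[smirks] = r
    return r


def _pattern(smarts):
    p = _pat_cache.get(smarts)
    if p is None:
        p = Chem.MolFromSmarts(smarts)
        _pat_cache[smarts] = p
    return p


def _clean_product(mol):
    """Sanitize a reaction-generated molecule; return canonical SMILES or None."""
    try:
        for atom in mol.GetAtoms():
            atom.SetAtomMapNum(0)
        Chem.SanitizeMol(mol)
        smi = Chem.MolToSmiles(mol)
        # round-trip to reject structures that only survive lax sanitization
        if Chem.MolFromSmiles(smi) is None:
            return None
        return smi
    except Exception:
        return None


def op_ping(req):
    return {"pong": True}


def op_canon(req):
    return {"result": [_canon(s) for s in req["smiles"]]}


def op_heavy(req):
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(None if m is None else m.GetNumHeavyAtoms())
    return {"result": out}


def op_nfrag(req):
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(None if m is None else len(Chem.GetMolFrags(m)))
    return {"result": out}


def op_match(req):
    pat = _pattern(req["smarts"])
    if pat is None:
        raise ValueError("bad SMARTS: %s" % req["smarts"])
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(None if m is None else m.HasSubstructMatch(pat))
    return {"result": out}


def op_valid_smirks(req):
    out = []
    for smk in req["smirks"]:
        try:
            r = rdChemReactions.ReactionFromSmarts(smk)
            if r is None:
                out.append({"ok": False, "reason": "unparsable"})
            else:
                out.append({"ok": True,
                            "n_lhs": r.GetNumReactantTemplates(),
                            "n_rhs": r.GetNumProductTemplates()})
        except Exception as e:
            out.append({"ok": False, "reason": str(e)})
    return {"result": out}


def op_retro(req):
    """Apply a retro SMIRKS (product pattern >> reactant patterns) to products.

    req: smirks, products (list of SMILES)
    result: per product, a list of reactant-sets, each a list of canonical
    SMILES in template reactant-pattern order; deduplicated per product.
    """
    rxn = _rxn(req["smirks"])
    if rxn is None:
        raise ValueError("bad SMIRKS")
    res = []
    for psmi in req["products"]:
        m = _mol(psmi)
        sets = []
        seen = set()
        if m is not None:
            try:
                outcomes = rxn.RunReactants((m,))
            except Exception:
                outcomes = ()
            for tup in outcomes:
                smis = [_clean_product(x) for x in tup]
                if any(s is None for s in smis):
                    continue
                if any(len(Chem.GetMolFrags(_mol(s))) != 1 for s in smis):
                    continue
                if psmi in smis:
                    continue  # degenerate: product among reactants
                key = tuple(sorted(smis))
                if key in seen:
                    continue
                seen.add(key)
                sets.append(smis)
        res.append(sets)
    return {"result": res}


def op_forward(req):
    """Apply a forward SMIRKS (reactant patterns >> product pattern).

    req: smirks, reactant_sets (list of lists of SMILES, template order)
    result: per set, list of distinct canonical product SMILES.
    """
    rxn = _rxn(req["smirks"])
    if rxn is None:
        raise ValueError("bad SMIRKS")
    res = []
    for rs in req["reactant_sets"]:
        mols = [_mol(s) for s in rs]
        prods = []
        seen = set()
        if all(m is not None for m in mols) and len(mols) == rxn.GetNumReactantTemplates():
            try:
                outcomes = rxn.RunReactants(tuple(mols))
            except Exception:
                outcomes = ()
            for tup in outcomes:
                if len(tup) != 1:
                    continue
                smi = _clean_product(tup[0])
                if smi is None or smi in seen:
                    continue
                if len(Chem.GetMolFrags(_mol(smi))) != 1:
                    continue
                seen.add(smi)
                prods.append(smi)
        res.append(prods)
    return {"result": res}


def op_match_many(req):
    """Boolean matrix: for each SMARTS, which SMILES contain it."""
    out = []
    for smarts in req["smarts"]:
        pat = _pattern(smarts)
        if pat is None:
            raise ValueError("bad SMARTS: %s" % smarts)
        row = []
        for s in req["smiles"]:
            m = _mol(s)
            row.append(None if m is None else m.HasSubstructMatch(pat))
        out.append(row)
    return {"result": out}


def op_retro_multi(req):
    """Apply several retro SMIRKS to one product; result parallel to smirks."""
    res = []
    for smk in req["smirks"]:
        sub = op_retro({"smirks": smk, "products": [req["product"]]})
        res.append(sub["result"][0])
    return {"result": res}


def op_morgan(req):
    """On-bit indices (0-based) of folded Morgan fingerprints."""
    nbits = int(req.get("nbits", 2048))
    radius = int(req.get("radius", 2))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            fp = gen.GetFingerprint(m)
            out.append(list(fp.GetOnBits()))
    return {"result": out}


OPS = {
    "ping": op_ping,
    "canon": op_canon,
    "heavy": op_heavy,
    "nfrag": op_nfrag,
    "match": op_match,
    "valid_smirks": op_valid_smirks,
    "retro": op_retro,
    "retro_multi": op_retro_multi,
    "match_many": op_match_many,
    "forward": op_forward,
    "morgan": op_morgan,
}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            fn = OPS.get(req.get("op"))
            if fn is None:
                resp = {"ok": False, "error": "unknown op: %r" % req.get("op")}
            else:
                resp = fn(req)
                resp["ok"] = True
        except Exception as e:
            resp = {"ok": False, "error": str(e)}
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
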