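{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "avmsim case configuration",
  "description": "AVM embolo-sclerotherapy case: vessel segments, nidus, fluid, boundary conditions, intervention stages and DSA flow measurements. Quantities use clinical units: mm (lengths/diameters), mmHg (pressures), ml/s (flows), mmHg.s/ml (resistances), m^2 (permeability), m^2/s (diffusivity).",
  "type": "object",
  "required": ["segments", "nidus", "fluid", "boundary", "stages"],
  "properties": {
    "segments": {
      "type": "array",
      "minItems": 3,
      "items": {
        "type": "object",
        "required": ["id", "kind", "diameter"],
        "properties": {
          "id": {"type": "string"},
          "kind": {"enum": ["feeding", "arterial_outlet", "venous", "internal"]},
          "diameter": {"type": "number", "exclusiveMinimum": 0, "description": "mm"},
          "length": {"type": ["number", "null"], "description": "mm; may be null when a lumped resistance is calibrated instead"}
        }
      }
    },
    "nidus": {
      "type": "object",
      "required": ["L", "W", "H"],
      "properties": {
        "L": {"type": "number", "exclusiveMinimum": 0, "description": "mm, streamwise"},
        "W": {"type": "number", "exclusiveMinimum": 0, "description": "mm"},
        "H": {"type": "number", "exclusiveMinimum": 0, "description": "mm"},
        "alpha": {"type": "number", "description": "calibrated shape factor, 1/m"}
      }
    },
    "fluid": {
      "type": "object",
      "required": ["density", "viscosity"],
      "properties": {
        "density": {"type": "number", "exclusiveMinimum": 0, "description": "kg/m^3"},
        "viscosity": {"type": "number", "exclusiveMinimum": 0, "description": "Pa.s"}
      }
    },
    "boundary": {
      "type": "object",
      "required": ["P_in", "R_art"],
      "properties": {
        "P_in": {"type": "number", "description": "inlet pressure, mmHg"},
        "R_art": {"type": "number", "minimum": 0, "description": "arterial outlet resistance, mmHg.s/ml"},
        "P_ven": {"type": "number", "default": 0, "description": "venous outlet pressure, mmHg"}
      }
    },
    "stages": {
      "type": "array",
      "minItems": 1,
      "description": "ordered, baseline first; each stage supplies R_nidus, K, or a Q_target for permeability calibration",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": {"type": "string"},
          "K": {"type": ["number", "null"], "description": "nidus permeability, m^2"},
          "R_nidus": {"type": ["number", "null"], "description": "mmHg.s/ml"},
          "Q_target": {"type": ["number", "null"], "description": "inlet-flow calibration target, ml/s"},
          "Q_nidus_target": {"type": ["number", "null"], "description": "nidus-flow calibration target (baseline), ml/s"}
        }
      }
    },
    "dsa_targets": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["stage", "Q_mean"],
        "properties": {
          "stage": {"type": "string"},
          "Q_mean": {"type": "number", "description": "ml/s"},
          "Q_sd": {"type": ["number", "null"], "description": "ml/s; null when only one measurement was usable"},
          "n": {"type": "integer", "minimum": 1}
        }
      }
    },
    "bolus": {
      "type": "object",
      "properties": {
        "amplitude": {"type": "number", "default": 1, "description": "kg/m^3"},
        "width": {"type": "number", "default": 1.5, "description": "s"},
        "total_time": {"type": "number", "default": 5, "description": "s"},
        "time_step": {"type": "number", "default": 0.01, "description": "s"}
      }
    },
    "dsa": {
      "type": "object",
      "properties": {
        "frame_rate": {"type": "number", "default": 2, "description": "frames/s"},
        "diffusivity": {"type": "number", "default": 2.2e-10, "description": "m^2/s"}
      }
    }
  }
}
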