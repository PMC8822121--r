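{
  "version": 1,
  "description": "Grasp-type / household-object pairing table of the grasping protocol. Each of the 10 grasp types is paired with exactly 3 of the 18 objects; labels are lowercase canonical names.",
  "grasps": [
    {"id": 1,  "name": "medium wrap",            "objects": ["bottle", "can", "door handle"]},
    {"id": 2,  "name": "lateral",                "objects": ["mug", "key", "pencil case"]},
    {"id": 3,  "name": "parallel extension",     "objects": ["plate", "book", "drawer"]},
    {"id": 4,  "name": "tripod grasp",           "objects": ["bottle", "mug", "drawer"]},
    {"id": 5,  "name": "power sphere",           "objects": ["ball", "bulb", "key"]},
    {"id": 6,  "name": "precision disk",         "objects": ["jar", "bulb", "ball"]},
    {"id": 7,  "name": "prismatic pinch",        "objects": ["clothespin", "key", "can"]},
    {"id": 8,  "name": "index finger extension", "objects": ["remote", "knife", "fork"]},
    {"id": 9,  "name": "adducted thumb",         "objects": ["screwdriver", "remote", "wrench"]},
    {"id": 10, "name": "prismatic four finger",  "objects": ["knife", "fork", "wrench"]}
  ],
  "non_graspable": ["person", "background"]
}
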